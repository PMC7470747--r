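test_that("population simulation is bitwise seed-deterministic", {
  cfg <- sim_config(n_isolates = 50, n_snps = 60, n_core_orfs = 20,
                    n_variable_orfs = 15, seed = 5)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$snp, b$snp)
  expect_identical(a$orf, b$orf)
  expect_identical(a$cno, b$cno)
})

test_that("the simulated site-frequency spectrum is rare-skewed", {
  cfg <- sim_config(n_isolates = 400, n_snps = 20000, seed = 6)
  sim <- simulate_population(cfg)
  maf <- apply(unclass(sim$snp), 2, function(x) {
    p <- mean(x) / 2
    min(p, 1 - p)
  })
  expect_gt(mean(maf < 0.1), 0.8)
})

test_that("pan-genome composition follows the configuration", {
  cfg <- sim_config(n_isolates = 60, n_snps = 50, n_core_orfs = 30,
                    n_variable_orfs = 0, seed = 7)
  sim <- simulate_population(cfg)
  expect_true(all(unclass(sim$orf) == 1))
  cfg2 <- sim_config(n_isolates = 200, n_snps = 50, n_core_orfs = 30,
                     n_variable_orfs = 40, seed = 8)
  sim2 <- simulate_population(cfg2)
  q <- colMeans(unclass(sim2$orf))
  expect_true(all(q[1:30] == 1))
  expect_true(all(q[31:70] < 1))
  # copy numbers: zero iff absent, bounded by cno_max
  cno <- unclass(sim2$cno)
  orf <- unclass(sim2$orf)
  expect_true(all((cno == 0) == (orf == 0)))
  expect_true(all(cno < 297))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(target_h2 = 1.5), "target_h2")
  expect_error(sim_config(cno_max = 400), "cno_max")
  expect_error(sim_config(orf_freq_range = c(0, 0.5)), "orf_freq_range")
})

test_that("realized heritability equals the target exactly in-sample", {
  for (h2 in c(0.2, 0.5, 0.8, 1)) {
    cfg <- sim_config(n_isolates = 120, n_snps = 200, causal_layer = "snp",
                      n_qtl = 40, target_h2 = h2, seed = 9)
    sim <- simulate_population(cfg)
    ph <- simulate_phenotype(sim, cfg)
    tr <- ph$truth
    expect_equal(tr$realized_h2, h2, tolerance = 1e-12)
    # bookkeeping identity: recompute from emitted data and effects
    X <- unclass(sim$snp)[, tr$causal_ids, drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    u <- drop(Xc %*% tr$effects)
    expect_equal(u, tr$u, tolerance = 1e-12)
    expect_equal(var(u) / (var(u) + var(ph$pheno$sim_trait - u)),
                 h2, tolerance = 1e-12)
  }
})

test_that("a zero-heritability trait is independent of every layer", {
  cfg <- sim_config(n_isolates = 150, n_snps = 200, target_h2 = 0, seed = 10)
  sim <- simulate_population(cfg)
  ph <- simulate_phenotype(sim, cfg)
  expect_equal(ph$truth$realized_h2, 0)
  expect_length(ph$truth$causal_ids, 0)
  y <- trait_vector(ph$pheno, "sim_trait")
  r <- cross_validate(y, snp_grm(sim$snp), cv_scheme(5, 2, seed = 1))
  # folds where the genetic component hits the zero boundary score r = 0
  expect_true(abs(r$mean_r) <= 3 * sd(r$fold_r) / sqrt(5) + 1e-12)
})

test_that("ORF-causal traits are better predicted by the ORF kernel", {
  cfg <- sim_config(n_isolates = 250, n_snps = 300, n_core_orfs = 50,
                    n_variable_orfs = 120, causal_layer = "orf",
                    n_qtl = 40, target_h2 = 0.6, seed = 11)
  sim <- simulate_population(cfg)
  ph <- simulate_phenotype(sim, cfg)
  y <- trait_vector(ph$pheno, "sim_trait")
  sch <- cv_scheme(5, 3, seed = 2)
  r_o <- cross_validate(y, orf_kernel(sim$orf), sch)$mean_r
  r_g <- cross_validate(y, snp_grm(sim$snp), sch)$mean_r
  expect_gt(r_o, r_g)
})

test_that("linkage coupling ties ORF presence to the SNP background", {
  base <- sim_config(n_isolates = 300, n_snps = 100, n_core_orfs = 5,
                     n_variable_orfs = 60, linkage = 0, seed = 12)
  linked <- sim_config(n_isolates = 300, n_snps = 100, n_core_orfs = 5,
                       n_variable_orfs = 60, linkage = 1, seed = 12)
  cancor_max <- function(sim) {
    o <- scale(unclass(sim$orf)[, -(1:5)])
    g <- scale(unclass(sim$snp))
    max(abs(cor(o, g)), na.rm = TRUE)
  }
  expect_gt(cancor_max(simulate_population(linked)),
            cancor_max(simulate_population(base)))
})

test_that("copy-number-borne traits favor CBLUP over GBLUP across datasets", {
  wins <- vapply(1:20, function(i) {
    cfg <- sim_config(n_isolates = 500, n_snps = 300, n_core_orfs = 60,
                      n_variable_orfs = 100, causal_layer = "cno",
                      n_qtl = 40, target_h2 = 0.6, seed = 300 + i)
    sim <- simulate_population(cfg)
    ph <- simulate_phenotype(sim, cfg)
    y <- trait_vector(ph$pheno, "sim_trait")
    sch <- cv_scheme(5, 1, seed = i)
    r_c <- cross_validate(y, cno_kernel(sim$cno), sch)$mean_r
    r_g <- cross_validate(y, snp_grm(sim$snp), sch)$mean_r
    r_c > r_g
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
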