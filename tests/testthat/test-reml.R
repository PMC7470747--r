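# One moderate population shared across REML tests
reml_pop <- local({
  cfg <- sim_config(n_isolates = 200, n_snps = 400, seed = 77)
  sim <- simulate_population(cfg)
  K <- kernel_eigen(snp_grm(sim$snp))
  list(sim = sim, K = K,
       cholV = chol(0.5 * K$K + diag(0.5, 200)))
})

test_that("restricted log-likelihood is non-decreasing across iterations", {
  set.seed(1)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y, reml_pop$K)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
  # two-kernel path too
  ko <- orf_kernel(reml_pop$sim$orf)
  fit2 <- panblup(y, list(reml_pop$K, ko))
  expect_true(all(diff(fit2$loglik_trace) >= -1e-10))
})

test_that("heritability is recovered from model-true simulations", {
  # moderate-n sanity version of the recovery study (full grid lives in
  # the acceptance suite)
  set.seed(2)
  h2_hat <- replicate(30, {
    y <- model_true_y(reml_pop$cholV, iso_ids(200))
    heritability(panblup(y, reml_pop$K))$value
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.07)
})

test_that("zero genetic signal drives the genetic component to the boundary", {
  set.seed(3)
  sg <- replicate(30, {
    y <- setNames(rnorm(200), iso_ids(200))
    coef(panblup(y, reml_pop$K))[["sigma2_g"]]
  })
  expect_lt(median(sg), 0.05)
})

test_that("heritability follows its definition and delta-method SE is finite", {
  set.seed(4)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y, reml_pop$K)
  th <- coef(fit)
  h <- heritability(fit)
  expect_equal(h$value, th[["sigma2_g"]] / sum(th))
  expect_equal(h$definition, "h2_G")
  expect_true(is.finite(h$se) && h$se > 0)
  # two-kernel definition sums the genetic components
  fit2 <- panblup(y, list(reml_pop$K, orf_kernel(reml_pop$sim$orf)))
  th2 <- coef(fit2)
  h2 <- heritability(fit2)
  expect_equal(h2$value, sum(th2[1:2]) / sum(th2))
  expect_equal(h2$definition, "h2_GO")
})

test_that("an identity-proportional kernel is flagged as non-identifiable", {
  K <- structure(list(K = diag(4), provenance = "G", scaling = 1,
                      freq = NULL), class = "pan_kernel")
  dimnames(K$K) <- list(letters[1:4], letters[1:4])
  y <- setNames(c(1, 2, 3, 4), letters[1:4])
  expect_warning(expect_warning(panblup(y, K), "fewer than 10"),
                 "not separable")
})

test_that("BLUP predictions shrink to zero as the genetic variance vanishes", {
  set.seed(5)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y, reml_pop$K)
  fit$components[["sigma2_g"]] <- 0
  expect_equal(unname(predict(fit, iso_ids(200)[1:10])), rep(0, 10))
})

test_that("in-sample BLUP satisfies g_hat = Gamma V^-1 (y - mu)", {
  set.seed(6)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y, reml_pop$K)
  th <- coef(fit)
  Gam <- th[[1]] * reml_pop$K$K
  V <- Gam + diag(th[[2]], 200)
  expect_equal(unname(predict(fit)),
               unname(drop(Gam %*% solve(V, fit$y - fit$mu))),
               tolerance = 1e-8)
  expect_equal(fitted(fit) + residuals(fit), fit$y)
})

test_that("prediction errors name isolates absent from the kernel", {
  set.seed(7)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y[1:150], reml_pop$K)
  expect_error(predict(fit, "ghost"), "ghost")
  # held-out isolates predict without error and carry signal on average
  pred <- predict(fit, iso_ids(200)[151:200])
  expect_length(pred, 50)
  rs <- replicate(10, {
    yr <- model_true_y(reml_pop$cholV, iso_ids(200))
    f <- panblup(yr[1:150], reml_pop$K)
    cor(predict(f, iso_ids(200)[151:200]), yr[151:200])
  })
  expect_gt(mean(rs), 0.1)
})

test_that("simulate() draws phenotypes whose h2 matches the fitted model", {
  set.seed(8)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  fit <- panblup(y, reml_pop$K)
  sims <- simulate(fit, nsim = 20, seed = 9)
  expect_equal(dim(sims), c(200L, 20L))
  h2_resim <- mean(vapply(sims, function(ys)
    heritability(panblup(setNames(ys, iso_ids(200)), reml_pop$K))$value,
    numeric(1)))
  expect_lt(abs(h2_resim - heritability(fit)$value), 0.15)
})

test_that("formula interface selects trait and kernels by name", {
  set.seed(10)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  ph <- data.frame(isolate = iso_ids(200), growth = unname(y))
  fit <- panblup(growth ~ G, data = ph, kernels = list(G = reml_pop$K))
  expect_equal(fit$model, "GBLUP")
  expect_equal(fit$trait, "growth")
  fit_direct <- panblup(y, reml_pop$K)
  expect_equal(coef(fit), coef(fit_direct))
  expect_error(panblup(growth ~ H, data = ph, kernels = list(G = reml_pop$K)),
               "not found")
})

test_that("model labels follow kernel provenance", {
  set.seed(11)
  y <- model_true_y(reml_pop$cholV, iso_ids(200))
  ko <- orf_kernel(reml_pop$sim$orf)
  kc <- cno_kernel(reml_pop$sim$cno)
  expect_equal(panblup(y, ko)$model, "OBLUP")
  expect_equal(panblup(y, kc)$model, "CBLUP")
  expect_equal(panblup(y, list(reml_pop$K, kc))$model, "GCBLUP")
})
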