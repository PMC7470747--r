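bayes_pop <- local({
  set.seed(123)
  X <- matrix(rbinom(100 * 300, 2, 0.3), 100, 300,
              dimnames = list(iso_ids(100), sprintf("m%03d", 1:300)))
  X
})

test_that("Gibbs chains are seed-deterministic", {
  y <- setNames(rnorm(100), rownames(bayes_pop))
  a <- bayes_fit(bayes_pop, y, model = "B", n_iter = 500, burn_in = 200,
                 seed = 42)
  b <- bayes_fit(bayes_pop, y, model = "B", n_iter = 500, burn_in = 200,
                 seed = 42)
  expect_identical(a$effects, b$effects)
  expect_identical(a$inclusion, b$inclusion)
  expect_identical(a$sigma2_e, b$sigma2_e)
})

test_that("Bayes B with pi = 1 collapses to Bayes A", {
  set.seed(13)
  y <- setNames(drop(scale(bayes_pop[, 1:40] %*% rnorm(40))) +
                  rnorm(100, sd = 0.5), rownames(bayes_pop))
  for (s in c(1, 2, 3)) {
    fa <- bayes_fit(bayes_pop, y, model = "A", n_iter = 1000, burn_in = 500,
                    seed = s)
    fb <- bayes_fit(bayes_pop, y, model = "B", pi_nonzero = 1,
                    n_iter = 1000, burn_in = 500, seed = s)
    expect_gt(cor(fa$effects, fb$effects), 0.99)
  }
})

test_that("a single causal column gets the largest effect and inclusion", {
  set.seed(14)
  n <- 200
  X <- matrix(rbinom(n * 100, 2, 0.4), n, 100,
              dimnames = list(iso_ids(n), sprintf("m%03d", 1:100)))
  xj <- X[, 37] - mean(X[, 37])
  g <- 2 * xj
  e <- rnorm(n)
  y <- setNames(g + e * sd(g) / (2 * sd(e)), rownames(X))  # h2 ~ 0.8
  fb <- bayes_fit(X, y, model = "B", n_iter = 2000, burn_in = 1000,
                  seed = 3)
  expect_equal(names(which.max(abs(fb$effects))), "m037")
  expect_equal(names(which.max(fb$inclusion)), "m037")
})

test_that("zero-signal inclusion probability recovers the prior pi", {
  set.seed(15)
  n <- 200
  X <- matrix(rbinom(n * 300, 2, 0.3), n, 300,
              dimnames = list(iso_ids(n), sprintf("m%03d", 1:300)))
  y <- setNames(rnorm(n), rownames(X))
  fb <- bayes_fit(X, y, model = "B", n_iter = 3000, burn_in = 1000,
                  seed = 11)
  mc_se <- sd(fb$inclusion) / sqrt(length(fb$inclusion))
  expect_lt(abs(mean(fb$inclusion) - 0.05), 3 * mc_se)
})

test_that("with the likelihood silenced, sigma2_j draws follow the prior", {
  # pin sigma2_e at 1e8 so every full conditional reduces to the prior,
  # thin to near-independence, and compare against direct
  # scaled-inv-chisq(5, 0.002) draws
  X <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(iso_ids(30), paste0("m", 1:5)))
  tr <- panblup:::bayes_sigma2_trace(X, rep(0, 30), "A",
                                     n_iter = 101000, burn_in = 1000,
                                     seed = 3, fix_sigma2e = 1e8,
                                     col = 1, thin = 10)
  expect_length(tr, 10000)
  set.seed(4)
  ref <- rscaled_inv_chisq(1e4, 5, 0.002)
  expect_gt(stats::ks.test(tr, ref)$p.value, 0.01)
})

test_that("posterior effects shrink toward zero as the prior scale shrinks", {
  set.seed(16)
  y <- setNames(drop(scale(bayes_pop[, 1:30] %*% rnorm(30))) + rnorm(100),
                rownames(bayes_pop))
  mean_abs <- vapply(c(2e-4, 2e-3, 2e-2), function(S)
    mean(abs(bayes_fit(bayes_pop, y, model = "A", scale_S = S,
                       n_iter = 1200, burn_in = 400, seed = 2)$effects)),
    numeric(1))
  expect_true(all(diff(mean_abs) > 0))
})

test_that("bayes predictions equal the explicit dot-product oracle", {
  set.seed(17)
  y <- setNames(rnorm(100), rownames(bayes_pop))
  fit <- bayes_fit(bayes_pop, y, model = "A", n_iter = 500, burn_in = 200,
                   seed = 1)
  Xnew <- bayes_pop[1:5, , drop = FALSE]
  oracle <- numeric(5)
  for (i in 1:5)
    oracle[i] <- fit$mu +
      sum((Xnew[i, ] - fit$centers) * fit$effects)
  expect_equal(unname(predict(fit, Xnew)), oracle, tolerance = 1e-12)
  # zero effects -> constant mu
  fit0 <- fit
  fit0$effects[] <- 0
  expect_equal(unname(predict(fit0, Xnew)), rep(fit$mu, 5))
  # column mismatch errors name the offender
  expect_error(predict(fit, Xnew[, -3]), "m003")
})

test_that("config errors are caught before sampling", {
  y <- setNames(rnorm(100), rownames(bayes_pop))
  expect_error(bayes_fit(bayes_pop, y, n_iter = 100, burn_in = 100),
               "burn_in")
  expect_error(bayes_fit(bayes_pop, y, pi_nonzero = 0), "pi_nonzero")
  Xz <- cbind(bayes_pop, const = 1)
  expect_warning(fz <- bayes_fit(Xz, y, n_iter = 300, burn_in = 100,
                                 seed = 1), "zero-variance")
  expect_equal(unname(fz$effects[["const"]]), 0)
})
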