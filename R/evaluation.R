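#' Cross-validation scheme
#'
#' @param k_folds number of folds (default 5).
#' @param n_replicates number of replicate random partitions (default 20).
#' @param seed integer seed.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(k_folds = 5, n_replicates = 20, seed = 1) {
  stopifnot(k_folds >= 2, n_replicates >= 1)
  structure(list(k_folds = k_folds, n_replicates = n_replicates, seed = seed),
            class = "cv_scheme")
}

# Fold assignments for one replicate, drawn over isolates in sorted-id order
# so the result depends only on the id set and the seed, not on input order.
.cv_folds <- function(ids, k, seed) {
  ids_sorted <- sort(ids)
  n <- length(ids_sorted)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fold <- sample(rep_len(seq_len(k), n))
  setNames(fold, ids_sorted)[ids]
}

#' Cross-validated predictive ability
#'
#' Measures predictive ability as the Pearson correlation between predicted
#' genetic values and observed phenotypes in held-out test folds, using
#' replicated k-fold random cross-validation (default 20 replicates of
#' 5-fold). For kernel predictors, variance components are re-estimated by
#' REML within every training fold (no leakage) and test isolates are
#' predicted by BLUP; for a Bayes predictor, the Gibbs sampler is rerun per
#' fold. Per-fold correlations are averaged (not pooled), so the default
#' scheme yields the mean over 100 estimates.
#'
#' @param y named phenotype vector.
#' @param predictor either a `pan_kernel` / list of kernels (BLUP path) or a
#'   list with elements `X` (predictor matrix) and Bayes settings
#'   (`model`, `n_iter`, `burn_in`, ...) for the Bayes path.
#' @param scheme a [cv_scheme].
#' @return object of class `predictive_ability`: per-fold correlations
#'   (`fold_r`, length k*replicates minus skipped folds), their mean
#'   (`mean_r`), the model label, and the scheme.
#' @export
cross_validate <- function(y, predictor, scheme = cv_scheme()) {
  y <- y[!is.na(y)]
  is_bayes <- is.list(predictor) && !inherits(predictor, "pan_kernel") &&
    !is.null(predictor$X)
  if (inherits(predictor, "pan_kernel")) predictor <- list(predictor)
  if (is_bayes) {
    ids <- intersect(names(y), rownames(predictor$X))
    label <- paste0("Bayes", predictor$model %||% "A")
  } else {
    ids <- names(y)
    for (k in predictor) ids <- ids[ids %in% rownames(k$K)]
    label <- .model_label(vapply(predictor, function(k) k$provenance,
                                 character(1)))
  }
  if (length(ids) < 2 * scheme$k_folds)
    stop("need at least 2*k_folds usable isolates")
  y <- y[ids]
  fold_r <- numeric(0)
  n_skipped <- 0L
  for (rep in seq_len(scheme$n_replicates)) {
    folds <- .cv_folds(ids, scheme$k_folds, scheme$seed + rep - 1L)
    for (f in seq_len(scheme$k_folds)) {
      test <- ids[folds == f]
      train <- ids[folds != f]
      if (sd(y[test]) == 0) {
        warning("constant test-fold phenotype; fold skipped")
        n_skipped <- n_skipped + 1L
        next
      }
      pred <- if (is_bayes) {
        fit <- bayes_fit(predictor$X[train, , drop = FALSE], y[train],
                         model = predictor$model %||% "A",
                         nu = predictor$nu %||% 5,
                         scale_S = predictor$scale_S %||% 0.002,
                         pi_nonzero = predictor$pi_nonzero %||% 0.05,
                         n_iter = predictor$n_iter %||% 2000,
                         burn_in = predictor$burn_in %||% 1000,
                         seed = scheme$seed + 1000L * rep + f)
        predict(fit, predictor$X[test, , drop = FALSE])
      } else {
        fit <- panblup(y[train], predictor)
        predict(fit, test)
      }
      # a constant prediction vector (all shrunk to the mean) has zero
      # predictive ability by definition; Pearson r is undefined there
      r <- if (sd(pred) == 0) 0 else cor(pred, y[test])
      fold_r <- c(fold_r, r)
    }
  }
  structure(list(model = label, fold_r = fold_r, mean_r = mean(fold_r),
                 n_skipped = n_skipped, scheme = scheme,
                 n_isolates = length(ids)),
            class = "predictive_ability")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.predictive_ability <- function(x, ...) {
  cat(sprintf("%s predictive ability: mean r = %.4f over %d fold estimates",
              x$model, x$mean_r, length(x$fold_r)),
      sprintf("(%d-fold x %d replicates, n = %d)\n", x$scheme$k_folds,
              x$scheme$n_replicates, x$n_isolates))
  invisible(x)
}

#' Predictive ability as a function of training-set size
#'
#' For each requested size `n`, draws `reps_per_size` random training
#' subsets of `n` isolates, fits the kernel model on each, predicts the
#' remaining isolates, and records the mean Pearson correlation between
#' predictions and observed phenotypes.
#'
#' @param y named phenotype vector.
#' @param kernels a `pan_kernel` or list of them.
#' @param sizes strictly increasing training-set sizes (the study design
#'   this mirrors used 200 to 600 in steps of 50).
#' @param reps_per_size random subsets per size (default 5).
#' @param seed integer seed.
#' @return object of class `train_size_series`: data.frame with columns
#'   `n_train` and `r` (mean predictive ability at that size).
#' @export
train_size_series <- function(y, kernels, sizes = seq(200, 600, by = 50),
                              reps_per_size = 5, seed = 1) {
  if (inherits(kernels, "pan_kernel")) kernels <- list(kernels)
  y <- y[!is.na(y)]
  ids <- names(y)
  for (k in kernels) ids <- ids[ids %in% rownames(k$K)]
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (max(sizes) >= length(ids))
    stop("largest training size must be smaller than the population (",
         length(ids), ")")
  y <- y[ids]
  ids_sorted <- sort(ids)
  out <- data.frame(n_train = sizes, r = NA_real_)
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    rs <- numeric(reps_per_size)
    for (rep in seq_len(reps_per_size)) {
      old <- local_seed(seed + 1000L * si + rep)
      train <- sample(ids_sorted, n)
      restore_seed(old)
      test <- setdiff(ids, train)
      fit <- panblup(y[train], kernels)
      pred <- predict(fit, test)
      rs[rep] <- cor(pred, y[test])
    }
    out$r[si] <- mean(rs, na.rm = TRUE)
  }
  structure(out, class = c("train_size_series", "data.frame"))
}

#' Fit the asymptotic accuracy curve r = w * sqrt(n h2 / (n h2 + Me))
#'
#' Fits the deterministic accuracy formula to an observed series of
#' (training size, predictive ability) points by maximum likelihood under
#' i.i.d. Gaussian residuals with free variance — equivalent to nonlinear
#' least squares. `w` is the asymptotic maximum predictive ability
#' (the curve's limit as n grows without bound) and `Me` the effective
#' number of independent chromosome segments. The optimizer is multistarted
#' from a coarse grid (`w` in 0.2..1.4, `Me` in \{50, 200, 1000, 3000\}) to
#' guard against the flat ridge this objective can exhibit; fits with
#' `w > 1`, or a fitted accuracy above 1 anywhere on the observed range, are
#' flagged as outliers rather than rejected.
#'
#' @param series a [train_size_series] or data.frame with columns `n_train`
#'   and `r` (at least 3 points).
#' @param h2 heritability plugged into the formula, in (0, 1].
#' @return object of class `accuracy_curve`: `w_hat`, `Me_hat`, `h2_used`,
#'   `R2_fit`, `outlier_flag`, `sse`, and the input series. Methods:
#'   `print`, `coef`, `predict` (accuracy at new training sizes), `plot`.
#' @examples
#' s <- data.frame(n_train = seq(200, 600, 50),
#'                 r = 0.8 * sqrt(seq(200, 600, 50) * 0.7 /
#'                                (seq(200, 600, 50) * 0.7 + 300)))
#' fit_accuracy_curve(s, h2 = 0.7)
#' @export
fit_accuracy_curve <- function(series, h2) {
  stopifnot(is.data.frame(series), all(c("n_train", "r") %in% names(series)))
  if (nrow(series) < 3) stop("need at least 3 (n_train, r) points")
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]")
  n <- series$n_train
  r <- series$r
  curve_fun <- function(w, Me) w * sqrt(n * h2 / (n * h2 + Me))
  sse <- function(par) {
    v <- r - curve_fun(par[1], exp(par[2]))  # Me on log scale, stays > 0
    sum(v * v)
  }
  starts <- expand.grid(w = seq(0.2, 1.4, by = 0.2),
                        logMe = log(c(50, 200, 1000, 3000)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(as.numeric(starts[i, ]), sse, method = "Nelder-Mead",
            control = list(reltol = 1e-14, maxit = 5000)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("accuracy-curve objective non-finite at all starts")
  # polish
  o2 <- tryCatch(optim(best$par, sse, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 2000)),
                 error = function(e) NULL)
  if (!is.null(o2) && is.finite(o2$value) && o2$value <= best$value) best <- o2
  w_hat <- best$par[1]
  Me_hat <- exp(best$par[2])
  fitted_r <- curve_fun(w_hat, Me_hat)
  sst <- sum((r - mean(r))^2)
  R2 <- if (sst > 0) 1 - best$value / sst else NA_real_
  structure(list(w_hat = w_hat, Me_hat = Me_hat, h2_used = h2,
                 R2_fit = R2, sse = best$value,
                 outlier_flag = (w_hat > 1) || any(fitted_r > 1),
                 series = series), class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf(
    "Accuracy curve fit (h2 = %.3f): w = %.4f, Me = %.1f, R2 = %.4f%s\n",
    x$h2_used, x$w_hat, x$Me_hat, x$R2_fit,
    if (x$outlier_flag) "  [outlier: fitted accuracy exceeds 1]" else ""))
  invisible(x)
}

#' @export
coef.accuracy_curve <- function(object, ...)
  c(w = object$w_hat, Me = object$Me_hat)

#' @rdname fit_accuracy_curve
#' @param object an `accuracy_curve` fit.
#' @param n_train training sizes at which to evaluate the fitted curve.
#' @param ... unused.
#' @export
predict.accuracy_curve <- function(object, n_train = object$series$n_train,
                                   ...) {
  object$w_hat * sqrt(n_train * object$h2_used /
                      (n_train * object$h2_used + object$Me_hat))
}

#' @rdname fit_accuracy_curve
#' @param x an `accuracy_curve` fit.
#' @export
plot.accuracy_curve <- function(x, ...) {
  s <- x$series
  plot(s$n_train, s$r, xlab = "training-set size n",
       ylab = "predictive ability r",
       main = sprintf("w = %.3f, Me = %.0f", x$w_hat, x$Me_hat), ...)
  ngrid <- seq(min(s$n_train), max(s$n_train), length.out = 200)
  graphics::lines(ngrid, predict(x, ngrid))
  invisible(x)
}
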