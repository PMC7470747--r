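#' Fit a kernel-based linear mixed model by REML
#'
#' Fits the model `y = 1*mu + g_1 + ... + g_k + e` with
#' `g_j ~ N(0, K_j * sigma_j^2)` and `e ~ N(0, I * sigma_e^2)`, where each
#' `K_j` is a relationship kernel built by [snp_grm()], [orf_kernel()] or
#' [cno_kernel()]. With a single kernel this is GBLUP / OBLUP / CBLUP
#' according to the kernel's provenance; with a SNP kernel plus an ORF or
#' copy-number kernel it is GOBLUP / GCBLUP. The overall mean is the only
#' fixed effect.
#'
#' Variance components are estimated by average-information (AI) REML with
#' step halving and an EM fallback, which guarantees a non-decreasing
#' restricted log-likelihood across iterations; negative proposals are
#' projected onto the boundary (component set to zero). Standard errors come
#' from the inverse AI matrix at the optimum. Single-kernel fits run in the
#' kernel's eigenbasis (O(n) per iteration after one decomposition, which is
#' reused when the kernel carries one from [kernel_eigen()]).
#'
#' @param y for the default method, a named numeric vector of phenotypes
#'   (names = isolate ids); isolates absent from any kernel are dropped.
#'   For the formula method, a formula `trait ~ K1 + K2` whose right-hand
#'   side names elements of `kernels`.
#' @param kernels a `pan_kernel` or list of them (one or two are the
#'   standard models; any number is accepted).
#' @param data for the formula method, a phenotype data.frame as returned by
#'   [read_phenotypes] (first column = isolate id).
#' @param max_iter maximum REML iterations (default 100).
#' @param tol relative restricted log-likelihood convergence tolerance
#'   (default 1e-8); components must also be stable to 1e-6 relative change.
#' @param ... passed between methods.
#' @return an object of class `panblup` with components `mu` (estimated
#'   mean), `components` (named variance components, residual last), `se`,
#'   `vcov_components`, `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `model` (label such as "GBLUP"), `y`, `ids`, and the kernels used.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `logLik`, `vcov`, `simulate`, and [heritability()].
#' @examples
#' set.seed(1)
#' sim <- simulate_population(sim_config(n_isolates = 80, n_snps = 150,
#'   seed = 7))
#' ph <- simulate_phenotype(sim, sim_config(n_isolates = 80, n_snps = 150,
#'   causal_layer = "snp", n_qtl = 30, target_h2 = 0.5, seed = 8))
#' fit <- panblup(trait_vector(ph$pheno, "sim_trait"), snp_grm(sim$snp))
#' heritability(fit)
#' @export
panblup <- function(y, ...) UseMethod("panblup")

#' @rdname panblup
#' @export
panblup.formula <- function(y, data, kernels, ...) {
  tf <- stats::terms(y)
  if (attr(tf, "response") != 1L) stop("formula needs a response (trait) term")
  trait <- as.character(attr(tf, "variables"))[2L]
  kn <- attr(tf, "term.labels")
  if (!all(kn %in% names(kernels)))
    stop("kernel(s) not found in 'kernels': ",
         paste(setdiff(kn, names(kernels)), collapse = ", "))
  fit <- panblup.default(trait_vector(data, trait), kernels[kn], ...)
  fit$trait <- trait
  fit
}

#' @rdname panblup
#' @export
panblup.default <- function(y, kernels, max_iter = 100, tol = 1e-8, ...) {
  if (inherits(kernels, "pan_kernel")) kernels <- list(kernels)
  stopifnot(length(kernels) >= 1L, all(vapply(kernels, inherits,
                                              logical(1), "pan_kernel")))
  if (is.null(names(y))) stop("y must be named by isolate id")
  y <- y[!is.na(y)]
  ids <- names(y)
  for (k in kernels) ids <- ids[ids %in% rownames(k$K)]
  if (length(ids) < length(y))
    message("panblup: dropped ", length(y) - length(ids),
            " isolate(s) absent from a kernel")
  if (length(ids) < 10L)
    warning("fewer than 10 usable isolates; variance components will be ",
            "poorly identified")
  yv <- as.numeric(y[ids])

  prov <- vapply(kernels, function(k) k$provenance, character(1))
  comp_names <- c(paste0("sigma2_", tolower(prov)), "sigma2_e")
  if (anyDuplicated(comp_names))
    comp_names <- c(paste0("sigma2_k", seq_along(kernels)), "sigma2_e")
  model_label <- .model_label(prov)

  Ktrain <- lapply(kernels, function(k) k$K[ids, ids, drop = FALSE])
  for (j in seq_along(Ktrain)) {
    K <- Ktrain[[j]]
    if (max(abs(K - diag(mean(diag(K)), nrow(K)))) < 1e-8)
      warning("kernel ", j, " is proportional to the identity: its variance ",
              "component is not separable from the residual")
  }

  cached_eigen <- if (identical(ids, rownames(kernels[[1L]]$K)))
    kernels[[1L]]$eigen else NULL
  eng <- if (length(Ktrain) == 1L)
    .reml_spectral(yv, Ktrain[[1L]], cached_eigen, max_iter, tol)
  else
    .reml_dense(yv, Ktrain, max_iter, tol)

  structure(list(
    call = match.call(), model = model_label, ids = ids,
    y = setNames(yv, ids), mu = eng$mu,
    components = setNames(eng$theta, comp_names),
    se = setNames(eng$se, comp_names),
    vcov_components = structure(eng$vcov,
                                dimnames = list(comp_names, comp_names)),
    loglik = eng$loglik, loglik_trace = eng$trace,
    converged = eng$converged, n_iter = eng$n_iter,
    kernels = kernels), class = "panblup")
}

.model_label <- function(prov) {
  key <- paste(sort(prov), collapse = "")
  switch(key, G = "GBLUP", O = "OBLUP", C = "CBLUP",
         GO = "GOBLUP", CG = "GCBLUP",
         paste0(paste(prov, collapse = "+"), "-BLUP"))
}

# ---- REML engines -----------------------------------------------------------

# Shared AI-REML outer loop. `fns` provides loglik/derivative callbacks on the
# component vector theta (genetic components first, residual last).
.reml_loop <- function(theta, fns, n, max_iter, tol, vy) {
  floor_e <- 1e-8 * vy
  clamp <- function(th) {
    th[-length(th)] <- pmax(th[-length(th)], 0)
    th[length(th)] <- max(th[length(th)], floor_e)
    th
  }
  theta <- clamp(theta)
  ll <- fns$loglik(theta)
  trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d <- fns$derivs(theta)
    dtheta <- tryCatch(solve(d$AI, d$score),
                       error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(dtheta)) {
      step <- 1
      for (h in 1:25) {
        thn <- clamp(theta + step * dtheta)
        lln <- fns$loglik(thn)
        if (is.finite(lln) && lln >= ll - 1e-10) { accepted <- TRUE; break }
        step <- step / 2
      }
    }
    if (!accepted) {
      # EM step: monotone but slow; used when the AI proposal fails
      thn <- theta
      k <- length(theta)
      em <- theta + theta^2 / n * (d$yPKPy - d$trPK)
      thn <- clamp(em)
      lln <- fns$loglik(thn)
      if (!is.finite(lln) || lln < ll - 1e-10) break  # stalled at optimum
    }
    rel_theta <- max(abs(thn - theta) / pmax(abs(theta), floor_e))
    done <- abs(lln - ll) < tol * (abs(ll) + 1) && rel_theta < 1e-6
    theta <- thn
    ll <- lln
    trace <- c(trace, ll)
    if (done) { converged <- TRUE; break }
  }
  if (!converged && it == max_iter)
    warning("REML did not converge in ", max_iter, " iterations")
  d <- fns$derivs(theta)
  vcov <- tryCatch(solve(d$AI), error = function(e) {
    solve(d$AI + diag(1e-8 * max(diag(d$AI)), nrow(d$AI)))
  })
  list(theta = theta, mu = fns$mu(theta), se = sqrt(pmax(diag(vcov), 0)),
       vcov = vcov, loglik = ll, trace = trace,
       converged = converged || it < max_iter, n_iter = it)
}

# Single-kernel REML in the kernel eigenbasis: all matrix functionals reduce
# to sums over eigenvalues.
.reml_spectral <- function(y, K, eig, max_iter, tol) {
  n <- length(y)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  ty <- drop(crossprod(U, y))
  tx <- drop(crossprod(U, rep(1, n)))
  vy <- var(y)

  base <- function(theta) {
    d <- theta[1] * lam + theta[2]
    xVx <- sum(tx^2 / d)
    beta <- sum(tx * ty / d) / xVx
    w <- ty / d - (tx / d) * beta           # P y in rotated coordinates
    yPy <- sum(ty * w)
    list(d = d, xVx = xVx, beta = beta, w = w, yPy = yPy)
  }
  Pv <- function(v, b) v / b$d - (tx / b$d) * (sum(tx * v / b$d) / b$xVx)

  fns <- list(
    loglik = function(theta) {
      b <- base(theta)
      -0.5 * (sum(log(b$d)) + log(b$xVx) + b$yPy)
    },
    derivs = function(theta) {
      b <- base(theta)
      trPK <- c(sum(lam / b$d) - sum(tx^2 * lam / b$d^2) / b$xVx,
                sum(1 / b$d) - sum(tx^2 / b$d^2) / b$xVx)
      u <- list(lam * b$w, b$w)              # K_j P y in rotated coordinates
      yPKPy <- c(sum(b$w * u[[1]]), sum(b$w * u[[2]]))
      AI <- matrix(0, 2, 2)
      Pu <- lapply(u, Pv, b = b)
      for (a in 1:2) for (bb in a:2)
        AI[a, bb] <- AI[bb, a] <- 0.5 * sum(u[[a]] * Pu[[bb]])
      list(score = -0.5 * (trPK - yPKPy), AI = AI,
           trPK = trPK, yPKPy = yPKPy)
    },
    mu = function(theta) base(theta)$beta)

  theta0 <- c(vy / 2 / max(mean(diag(K)), 1e-12), vy / 2)
  .reml_loop(theta0, fns, n, max_iter, tol, vy)
}

# Dense AI-REML for two or more kernels.
.reml_dense <- function(y, Klist, max_iter, tol) {
  n <- length(y)
  k <- length(Klist)
  vy <- var(y)
  ones <- rep(1, n)

  base <- function(theta) {
    V <- diag(theta[k + 1], n)
    for (j in seq_len(k)) V <- V + theta[j] * Klist[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      message("REML: V not positive definite; applying one-time diagonal ",
              "boost of 1e-6 * mean(diag)")
      V <- V + diag(1e-6 * mean(diag(V)), n)
      ch <- chol(V)
    }
    Vi <- chol2inv(ch)
    a <- Vi %*% ones
    xVx <- sum(a)
    P <- Vi - tcrossprod(a) / xVx
    beta <- sum(a * y) / xVx
    Py <- drop(P %*% y)
    list(ch = ch, P = P, beta = beta, Py = Py, yPy = sum(y * Py), xVx = xVx)
  }

  fns <- list(
    loglik = function(theta) {
      b <- base(theta)
      -0.5 * (2 * sum(log(diag(b$ch))) + log(b$xVx) + b$yPy)
    },
    derivs = function(theta) {
      b <- base(theta)
      u <- vector("list", k + 1)
      trPK <- numeric(k + 1)
      for (j in seq_len(k)) {
        trPK[j] <- sum(b$P * Klist[[j]])
        u[[j]] <- drop(Klist[[j]] %*% b$Py)
      }
      trPK[k + 1] <- sum(diag(b$P))
      u[[k + 1]] <- b$Py
      yPKPy <- vapply(u, function(v) sum(b$Py * v), numeric(1))
      Pu <- lapply(u, function(v) drop(b$P %*% v))
      AI <- matrix(0, k + 1, k + 1)
      for (a in seq_len(k + 1)) for (bb in a:(k + 1))
        AI[a, bb] <- AI[bb, a] <- 0.5 * sum(u[[a]] * Pu[[bb]])
      list(score = -0.5 * (trPK - yPKPy), AI = AI,
           trPK = trPK, yPKPy = yPKPy)
    },
    mu = function(theta) base(theta)$beta)

  theta0 <- c(vapply(Klist, function(K)
    vy / (2 * k) / max(mean(diag(K)), 1e-12), numeric(1)), vy / 2)
  .reml_loop(theta0, fns, n, max_iter, tol, vy)
}

# ---- methods ----------------------------------------------------------------

#' @export
print.panblup <- function(x, ...) {
  cat(x$model, "fit by AI-REML:", length(x$ids), "isolates\n")
  cat("  mu =", format(x$mu, digits = 4), "\n  components:\n")
  print(round(x$components, 5))
  h <- heritability(x)
  cat(sprintf("  h2 = %.4f (SE %.4f)   logLik = %.4f   %s\n",
              h$value, h$se, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.panblup <- function(object, ...) object$components

#' @export
vcov.panblup <- function(object, ...) object$vcov_components

#' @export
logLik.panblup <- function(object, ...) {
  structure(object$loglik, df = length(object$components) + 1,
            nobs = length(object$y), class = "logLik")
}

#' @export
summary.panblup <- function(object, ...) {
  h <- heritability(object)
  structure(list(fit = object, h2 = h), class = "summary.panblup")
}

#' @export
print.summary.panblup <- function(x, ...) {
  f <- x$fit
  cat(f$model, "linear mixed model (REML)\n")
  cat("Isolates:", length(f$ids), "  Iterations:", f$n_iter,
      "  Converged:", f$converged, "\n\n")
  tab <- cbind(Estimate = f$components, `Std. Error` = f$se)
  print(round(tab, 5))
  cat(sprintf("\nOverall mean: %.5f\nRestricted logLik: %.5f\n",
              f$mu, f$loglik))
  cat(sprintf("%s = %.4f (SE %.4f)\n", x$h2$definition, x$h2$value, x$h2$se))
  invisible(x)
}

#' BLUP genetic values for training or new isolates
#'
#' Computes `g_hat = Gamma[ids, train] %*% solve(V_train, y - mu)` where
#' `Gamma = sum_j sigma_j^2 K_j` over the fitted genetic kernels and
#' `V_train = Gamma[train, train] + sigma_e^2 I`. Any isolate present in all
#' kernels can be predicted, trained-on or not.
#'
#' @param object a `panblup` fit.
#' @param ids isolate ids to predict (default: the training isolates).
#' @param ... unused.
#' @return named numeric vector of predicted genetic values (deviations from
#'   the overall mean `mu`).
#' @export
predict.panblup <- function(object, ids = NULL, ...) {
  train <- object$ids
  if (is.null(ids)) ids <- train
  for (k in object$kernels) {
    absent <- setdiff(ids, rownames(k$K))
    if (length(absent))
      stop("isolate(s) absent from kernel: ",
           paste(head(absent, 5), collapse = ", "))
  }
  theta <- object$components
  k <- length(object$kernels)
  n <- length(train)
  Gtt <- matrix(0, n, n)
  Gpt <- matrix(0, length(ids), n)
  for (j in seq_len(k)) {
    K <- object$kernels[[j]]$K
    Gtt <- Gtt + theta[j] * K[train, train, drop = FALSE]
    Gpt <- Gpt + theta[j] * K[ids, train, drop = FALSE]
  }
  V <- Gtt + diag(theta[k + 1], n)
  alpha <- tryCatch(solve(V, object$y - object$mu), error = function(e) {
    solve(V + diag(1e-6 * mean(diag(V)), n), object$y - object$mu)
  })
  setNames(drop(Gpt %*% alpha), ids)
}

#' @export
fitted.panblup <- function(object, ...) object$mu + predict(object)

#' @export
residuals.panblup <- function(object, ...) object$y - fitted(object)

#' Simulate phenotypes from a fitted model
#'
#' Draws `nsim` response vectors from `N(1*mu, sum_j sigma_j^2 K_j +
#' sigma_e^2 I)` at the training isolates.
#'
#' @param object a `panblup` fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed (optional).
#' @param ... unused.
#' @return data.frame, one column per simulation, rownames = isolate ids.
#' @export
simulate.panblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  train <- object$ids
  n <- length(train)
  theta <- object$components
  k <- length(object$kernels)
  V <- diag(theta[k + 1], n)
  for (j in seq_len(k))
    V <- V + theta[j] * object$kernels[[j]]$K[train, train, drop = FALSE]
  ch <- tryCatch(chol(V), error = function(e)
    chol(V + diag(1e-8 * mean(diag(V)), n)))
  out <- object$mu + crossprod(ch, matrix(rnorm(n * nsim), n, nsim))
  out <- as.data.frame(out, row.names = train)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Kernel-based heritability from a fitted mixed model
#'
#' The ratio of the summed genetic variance components to the total
#' (genetic + residual) variance: `h2 = sum(sigma_g^2) / (sum(sigma_g^2) +
#' sigma_e^2)`. For single-kernel fits this is the SNP-, ORF- or CNO-based
#' heritability (h2_G, h2_O, h2_C) according to the kernel provenance; for
#' two-kernel fits the joint definition (h2_GO, h2_GC). The standard error
#' is obtained by the delta method on the component covariance matrix from
#' the average-information matrix.
#'
#' @param fit a `panblup` fit.
#' @return object of class `heritability_estimate`: list with `value`, `se`
#'   and `definition`.
#' @export
heritability <- function(fit) {
  stopifnot(inherits(fit, "panblup"))
  theta <- fit$components
  k <- length(theta) - 1L
  Sg <- sum(theta[seq_len(k)])
  Tt <- Sg + theta[k + 1]
  if (Tt <= 0) {
    value <- 0
    se <- NA_real_
  } else {
    value <- Sg / Tt
    grad <- c(rep(theta[k + 1] / Tt^2, k), -Sg / Tt^2)
    se <- sqrt(max(0, drop(t(grad) %*% fit$vcov_components %*% grad)))
  }
  if (theta[k + 1] <= 1e-7 * Tt)
    warning("residual variance estimated at the zero boundary; ",
            "heritability reported as ~1 from a degenerate fit")
  prov <- vapply(fit$kernels, function(x) x$provenance, character(1))
  defn <- paste0("h2_", paste(sort(prov, decreasing = FALSE), collapse = ""))
  structure(list(value = as.numeric(value), se = as.numeric(se),
                 definition = defn), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (SE %.4f)\n", x$definition, x$value, x$se))
  invisible(x)
}
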