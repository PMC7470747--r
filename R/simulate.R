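#' Configuration for the synthetic pan-genome simulator
#'
#' The defaults emulate the salient features of the yeast pan-genome data
#' this toolkit targets, scaled to desk size: a rare-skewed site frequency
#' spectrum (Beta(0.3, 3) allele frequencies put the large majority of
#' minor allele frequencies below 0.1), a pan-genome that is roughly 63%
#' core ORFs (present in every isolate) and 37% variable ORFs with presence
#' frequency uniform on `orf_freq_range`, and ORF copy numbers that are 0
#' where an ORF is absent, mostly 1-2 where present, with occasional larger
#' amplifications bounded by `cno_max = 296`.
#'
#' @param n_isolates,n_snps population and SNP panel size.
#' @param maf_beta_params shape parameters of the Beta distribution the
#'   per-SNP allele frequencies are drawn from.
#' @param n_core_orfs,n_variable_orfs pan-genome composition.
#' @param orf_freq_range presence-frequency range of variable ORFs, inside
#'   (0, 1).
#' @param cno_max upper bound for simulated copy numbers (must stay below
#'   297).
#' @param causal_layer which layer carries the causal columns for
#'   [simulate_phenotype]: `"snp"`, `"orf"` or `"cno"`.
#' @param n_qtl number of causal columns.
#' @param target_h2 heritability of the simulated trait, attained exactly
#'   in-sample (residuals are scaled so the realized variance ratio equals
#'   the target).
#' @param linkage optional coupling strength in (0, 1]; when positive, each
#'   variable ORF's presence probability follows a logistic function of a
#'   local SNP score, tying the ORF layer to the SNP background. Default 0
#'   (layers independent).
#' @param seed integer seed; all draws are deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_isolates = 500, n_snps = 1000,
                       maf_beta_params = c(0.15, 4),
                       n_core_orfs = 250, n_variable_orfs = 150,
                       orf_freq_range = c(0.05, 0.95), cno_max = 296,
                       causal_layer = c("snp", "orf", "cno"), n_qtl = 50,
                       target_h2 = 0.5, linkage = 0, seed = 1) {
  causal_layer <- match.arg(causal_layer)
  if (!(target_h2 >= 0 && target_h2 <= 1)) stop("target_h2 must be in [0, 1]")
  if (cno_max >= 297) stop("cno_max must be below 297")
  if (orf_freq_range[1] <= 0 || orf_freq_range[2] >= 1 ||
      orf_freq_range[1] > orf_freq_range[2])
    stop("orf_freq_range must be inside (0, 1)")
  if (linkage < 0 || linkage > 1) stop("linkage must be in [0, 1]")
  structure(list(n_isolates = n_isolates, n_snps = n_snps,
                 maf_beta_params = maf_beta_params,
                 n_core_orfs = n_core_orfs,
                 n_variable_orfs = n_variable_orfs,
                 orf_freq_range = orf_freq_range, cno_max = cno_max,
                 causal_layer = causal_layer, n_qtl = n_qtl,
                 target_h2 = target_h2, linkage = linkage, seed = seed),
            class = "sim_config")
}

#' Simulate a synthetic pan-genome population
#'
#' Draws the three predictor layers under the architecture described in
#' [sim_config]: SNP dosages are per-marker Binomial(2, p) with p from the
#' configured Beta distribution; variable ORFs are Bernoulli with
#' column-specific presence frequency (optionally coupled to a local SNP
#' score via the `linkage` parameter); copy numbers are 0 where an ORF is
#' absent and `1 + Poisson(0.3)` where present, with rare amplification
#' events adding up to `cno_max` total copies.
#'
#' @param config a [sim_config].
#' @return list with elements `snp` ([genotype_matrix]), `orf`
#'   ([orf_matrix]) and `cno` ([cno_matrix]), all over the same isolates.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  n <- config$n_isolates
  iso <- sprintf("iso%04d", seq_len(n))

  p <- rbeta(config$n_snps, config$maf_beta_params[1],
             config$maf_beta_params[2])
  snp <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  dimnames(snp) <- list(iso, sprintf("snp%05d", seq_len(config$n_snps)))

  n_orf <- config$n_core_orfs + config$n_variable_orfs
  orf <- matrix(1, n, n_orf,
                dimnames = list(iso, sprintf("orf%04d", seq_len(n_orf))))
  if (config$n_variable_orfs > 0) {
    q <- runif(config$n_variable_orfs, config$orf_freq_range[1],
               config$orf_freq_range[2])
    vcols <- config$n_core_orfs + seq_len(config$n_variable_orfs)
    if (config$linkage > 0 && config$n_snps >= 5) {
      # presence probability logistic in a local SNP score, so ORF status
      # carries SNP-background information
      for (j in seq_along(vcols)) {
        anchor <- sample(seq_len(config$n_snps - 4), 1)
        score <- scale(rowMeans(snp[, anchor:(anchor + 4), drop = FALSE]))
        eta <- qlogis(q[j]) + 3 * config$linkage * drop(score)
        orf[, vcols[j]] <- rbinom(n, 1, plogis(eta))
      }
    } else {
      for (j in seq_along(vcols))
        orf[, vcols[j]] <- rbinom(n, 1, q[j])
    }
  }

  cno <- matrix(0, n, n_orf, dimnames = dimnames(orf))
  present <- orf == 1
  n_present <- sum(present)
  base <- 1 + rpois(n_present, 0.3)
  amp <- rbinom(n_present, 1, 0.01) * sample(1:20, n_present, replace = TRUE)
  cno[present] <- pmin(base + amp, config$cno_max)

  list(snp = genotype_matrix(snp), orf = orf_matrix(orf),
       cno = cno_matrix(cno))
}

#' Simulate a phenotype with known architecture
#'
#' Chooses `n_qtl` causal columns from the configured layer, draws their
#' effects from N(0, 1), forms genetic values `u = X_centered %*% effects`
#' (columns centered as in the corresponding kernel), and adds Gaussian
#' residuals scaled so that the realized in-sample heritability
#' `Var(u) / (Var(u) + Var(e))` equals `target_h2` exactly. With
#' `target_h2 = 0` the phenotype is pure noise, independent of all layers.
#'
#' @param matrices list as returned by [simulate_population].
#' @param config a [sim_config]; its `causal_layer`, `n_qtl`, `target_h2`
#'   and `seed` fields drive the draw (the seed is offset from the one used
#'   for the population so genotypes and effects are independent).
#' @return list with `pheno` (data.frame: `isolate`, `sim_trait`) and
#'   `truth` (causal ids, effects, genetic values `u`, residuals,
#'   `realized_h2`).
#' @export
simulate_phenotype <- function(matrices, config) {
  stopifnot(inherits(config, "sim_config"))
  layer <- switch(config$causal_layer, snp = matrices$snp,
                  orf = matrices$orf, cno = matrices$cno)
  if (is.null(layer)) stop("causal layer '", config$causal_layer,
                           "' absent from matrices")
  X <- unclass(layer)
  n <- nrow(X)
  old <- local_seed(config$seed + 104729L)  # distinct stream from genotypes
  on.exit(restore_seed(old))

  h2 <- config$target_h2
  if (h2 == 0) {
    u <- rep(0, n)
    causal <- character(0)
    effects <- numeric(0)
    e <- rnorm(n)
  } else {
    variable <- which(apply(X, 2, function(x) var(x) > 0))
    if (length(variable) < config$n_qtl)
      stop("fewer variable columns (", length(variable),
           ") than requested QTL (", config$n_qtl, ")")
    idx <- sample(variable, config$n_qtl)
    causal <- colnames(X)[idx]
    effects <- rnorm(config$n_qtl)
    Xc <- sweep(X[, idx, drop = FALSE], 2, colMeans(X[, idx, drop = FALSE]))
    u <- drop(Xc %*% effects)
    if (var(u) <= 0)
      stop("causal columns carry no genetic variance; cannot reach target_h2")
    e <- rnorm(n)
    e <- e - mean(e)
    if (h2 == 1) e <- rep(0, n)
    else e <- e * sqrt(var(u) * (1 - h2) / h2 / var(e))
  }
  y <- u + e
  realized <- if (h2 == 0) 0 else var(u) / (var(u) + var(e))
  list(pheno = data.frame(isolate = rownames(X), sim_trait = y),
       truth = list(causal_ids = causal, effects = effects, u = u,
                    residuals = e, realized_h2 = realized,
                    layer = config$causal_layer))
}
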