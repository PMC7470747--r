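#' Quality filters for SNP genotype matrices
#'
#' Applies the standard marker QC chain in a fixed order, each criterion on
#' the survivors of the previous one:
#' 1. missing rate: markers with a fraction of missing calls above
#'    `max_missing` are removed;
#' 2. minor allele frequency: markers with MAF below `min_maf` (computed on
#'    non-missing calls) are removed;
#' 3. Hardy-Weinberg equilibrium: markers whose observed genotype counts
#'    deviate from the expected n*(p^2, 2pq, q^2) by a 1-df chi-square test
#'    with p-value below `hwe_alpha` are removed.
#'
#' @param G a [genotype_matrix].
#' @param max_missing maximum tolerated missing-call fraction (default 0.05).
#' @param min_maf minimum minor allele frequency (default 0.01); markers with
#'   MAF exactly at the threshold are kept.
#' @param hwe_alpha HWE chi-square p-value threshold (default 1e-6).
#' @return list with elements `matrix` (the filtered [genotype_matrix]) and
#'   `report` (a [filter_report]).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0, 0, 0), 3, 2,
#'   dimnames = list(paste0("i", 1:3), c("m1", "m2"))))
#' filter_snps(g)$report
#' @export
filter_snps <- function(G, max_missing = 0.05, min_maf = 0.01,
                        hwe_alpha = 1e-6) {
  stopifnot(inherits(G, "genotype_matrix"))
  stages <- list()
  keep <- colnames(G)
  m <- unclass(G)

  miss <- colMeans(is.na(m))
  drop1 <- keep[miss[keep] > max_missing]
  keep <- setdiff(keep, drop1)
  stages$missing_rate <- list(removed = drop1, retained = length(keep))

  maf <- apply(m[, keep, drop = FALSE], 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  drop2 <- keep[maf < min_maf]
  keep <- setdiff(keep, drop2)
  stages$maf <- list(removed = drop2, retained = length(keep))

  hwe_p <- apply(m[, keep, drop = FALSE], 2, hwe_chisq_p)
  drop3 <- keep[hwe_p < hwe_alpha]
  keep <- setdiff(keep, drop3)
  stages$hwe <- list(removed = drop3, retained = length(keep))

  if (length(keep) == 0L) stop("all markers removed by filtering")
  out <- m[, keep, drop = FALSE]
  ca <- attr(G, "counted_allele")
  if (!is.null(ca)) ca <- ca[match(keep, colnames(G))]
  list(matrix = genotype_matrix(out, counted_allele = ca),
       report = filter_report(ncol(G), stages))
}

# 1-df chi-square p-value for HWE from a vector of 0/1/2 dosages (NA dropped);
# monomorphic markers carry no test and return 1.
hwe_chisq_p <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)  # frequency of counted allele
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((obs - expd)^2 / expd)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Frequency filter for ORF presence/absence and copy-number matrices
#'
#' For an [orf_matrix] the frequency of a column is its presence fraction
#' `q`; only rare ORFs (`q < min_freq`) are removed, so core ORFs (`q = 1`)
#' are always retained (they carry zero weight in the O kernel because
#' `q(1-q) = 0`). For a [cno_matrix] the frequency is the fraction of
#' isolates whose copy number differs from the column's modal value; columns
#' below `min_freq` are removed.
#'
#' @param M an [orf_matrix] or [cno_matrix].
#' @param min_freq minimum frequency (default 0.05); columns exactly at the
#'   threshold are kept.
#' @return list with elements `matrix` and `report` as in [filter_snps];
#'   an empty result is returned with a warning, not an error.
#' @export
filter_by_frequency <- function(M, min_freq = 0.05) {
  if (inherits(M, "orf_matrix")) {
    fr <- colMeans(unclass(M))
    keep <- fr >= min_freq
    rebuild <- orf_matrix
  } else if (inherits(M, "cno_matrix")) {
    fr <- apply(unclass(M), 2, function(x) {
      tab <- table(x)
      mode_val <- as.numeric(names(tab)[which.max(tab)])
      mean(x != mode_val)
    })
    keep <- fr >= min_freq
    rebuild <- cno_matrix
  } else stop("M must be an orf_matrix or cno_matrix")
  removed <- colnames(M)[!keep]
  if (!any(keep)) warning("frequency filter removed every column")
  out <- unclass(M)[, keep, drop = FALSE]
  stages <- list(frequency = list(removed = removed, retained = sum(keep)))
  mat <- if (any(keep)) rebuild(out) else structure(out, class = class(M))
  list(matrix = mat, report = filter_report(ncol(M), stages))
}

#' Impute missing SNP genotypes by marker-wise frequency sampling
#'
#' Each missing call is drawn from the marker's observed genotype-frequency
#' distribution (the empirical distribution of its non-missing 0/1/2 calls).
#' This deliberately ignores linkage disequilibrium; it is intended for the
#' low missing rates left after [filter_snps]. The draw is deterministic
#' given `seed`.
#'
#' @param G a [genotype_matrix].
#' @param seed integer seed.
#' @return a [genotype_matrix] with no missing values.
#' @export
impute_missing <- function(G, seed) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- unclass(G)
  if (!anyNA(m)) return(G)
  full_miss <- colSums(!is.na(m)) == 0L
  if (any(full_miss))
    stop("marker(s) entirely missing: ",
         paste(head(colnames(m)[full_miss], 5), collapse = ", "))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (j in which(colSums(is.na(m)) > 0L)) {
    x <- m[, j]
    obs <- x[!is.na(x)]
    na_idx <- which(is.na(x))
    m[na_idx, j] <- sample(obs, length(na_idx), replace = TRUE)
  }
  genotype_matrix(m, counted_allele = attr(G, "counted_allele"))
}

#' Filter report bookkeeping
#'
#' Records, per filter stage, which columns were removed; the conservation
#' invariant retained + removed = input holds at every stage.
#'
#' @param n_input number of input columns.
#' @param stages named list; each element has `removed` (character ids) and
#'   `retained` (count after the stage).
#' @return object of class `filter_report`.
#' @export
filter_report <- function(n_input, stages) {
  n <- n_input
  for (s in names(stages)) {
    st <- stages[[s]]
    if (length(st$removed) + st$retained != n)
      stop("filter_report: removed + retained != input at stage ", s)
    n <- st$retained
  }
  structure(list(n_input = n_input, n_retained = n, stages = stages),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report:", x$n_input, "columns in,", x$n_retained, "retained\n")
  for (s in names(x$stages))
    cat(sprintf("  %-14s removed %d\n", s, length(x$stages[[s]]$removed)))
  invisible(x)
}

# Seed handling that restores the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
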