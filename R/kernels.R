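#' Relationship kernels from pan-genome predictor layers
#'
#' A `pan_kernel` is a symmetric isolate-by-isolate covariance matrix built
#' from one predictor layer, together with its provenance and the scaling
#' constant used:
#'
#' * `snp_grm()` builds the SNP genomic relationship matrix
#'   `G = ZZ' / (2 * sum p_i (1 - p_i))`, where `Z` is the dosage matrix
#'   column-centered at `2 p_i` and `p_i` is the minor allele frequency of
#'   marker `i`. Columns whose stored dosage counts the major allele are
#'   flipped (`x -> 2 - x`) first, so the 0/1/2 code always counts the minor
#'   allele and the centering is internally consistent.
#' * `orf_kernel()` builds `O = WW' / sum q_i (1 - q_i)` from ORF
#'   presence/absence, `W` centered at the presence frequency `q_i`. Core
#'   ORFs (`q = 1`) contribute zero to numerator and denominator.
#' * `cno_kernel()` builds `C = SS' / f` from ORF copy numbers, `S` centered
#'   at the column mean `u_i` and `f` the median of `diag(SS')` — so the
#'   median diagonal element of `C` is exactly 1.
#'
#' All three kernels have zero row sums (every column of the centered
#' predictor matrix sums to zero) and are positive semi-definite up to
#' numerical tolerance. Monomorphic SNPs and core ORFs are silently
#' zero-weight rather than rejected, so the same code path serves filtered
#' and unfiltered inputs; an error is raised only when *no* column carries
#' weight, which would make the scaling constant zero.
#'
#' @param G a [genotype_matrix] without missing values (impute first).
#' @param W an [orf_matrix].
#' @param B a [cno_matrix].
#' @return a `pan_kernel`: list with `K` (n x n symmetric matrix with isolate
#'   dimnames), `provenance` (`"G"`, `"O"` or `"C"`), `scaling` (the
#'   denominator used) and `freq` (the per-column frequency/mean vector).
#' @examples
#' g <- genotype_matrix(matrix(c(0, 2), 2, 1,
#'   dimnames = list(c("a", "b"), "m1")))
#' snp_grm(g)$K        # [[2,-2],[-2,2]]
#' @name kernels
NULL

new_pan_kernel <- function(K, provenance, scaling, freq) {
  dimnames(K) <- list(rownames(K), rownames(K))
  structure(list(K = K, provenance = provenance, scaling = scaling,
                 freq = freq),
            class = "pan_kernel")
}

#' @rdname kernels
#' @export
snp_grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- unclass(G)
  if (anyNA(m)) stop("genotype matrix has missing values; run impute_missing() first")
  p <- colMeans(m) / 2
  flip <- p > 0.5
  if (any(flip)) {
    m[, flip] <- 2 - m[, flip]
    p[flip] <- 1 - p[flip]
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic: SNP kernel denominator is zero")
  Z <- sweep(m, 2, 2 * p, "-")
  new_pan_kernel(tcrossprod(Z) / denom, "G", denom, p)
}

#' @rdname kernels
#' @export
orf_kernel <- function(W) {
  stopifnot(inherits(W, "orf_matrix"))
  m <- unclass(W)
  q <- colMeans(m)
  denom <- sum(q * (1 - q))
  if (denom <= 0)
    stop("no variable ORFs: ORF kernel denominator is zero")
  Wc <- sweep(m, 2, q, "-")
  new_pan_kernel(tcrossprod(Wc) / denom, "O", denom, q)
}

#' @rdname kernels
#' @export
cno_kernel <- function(B) {
  stopifnot(inherits(B, "cno_matrix"))
  m <- unclass(B)
  u <- colMeans(m)
  S <- sweep(m, 2, u, "-")
  SS <- tcrossprod(S)
  f <- median(diag(SS))
  if (f <= 0)
    stop("copy-number kernel scaling constant is zero (isolates identical)")
  new_pan_kernel(SS / f, "C", f, u)
}

#' @export
print.pan_kernel <- function(x, ...) {
  cat(sprintf("pan_kernel [%s]: %d isolates, scaling constant %.6g\n",
              x$provenance, nrow(x$K), x$scaling))
  invisible(x)
}

#' Subset a kernel to a set of isolates
#'
#' @param x a `pan_kernel`.
#' @param ids isolate ids to keep (order respected).
#' @param ... unused.
#' @export
`[.pan_kernel` <- function(x, ids, ...) {
  missing_ids <- setdiff(ids, rownames(x$K))
  if (length(missing_ids))
    stop("isolate(s) absent from kernel: ",
         paste(head(missing_ids, 5), collapse = ", "))
  out <- x
  out$K <- x$K[ids, ids, drop = FALSE]
  out$eigen <- NULL
  out
}

#' Attach a spectral decomposition to a kernel
#'
#' Eigendecomposes `K` once and stores the result on the kernel object.
#' Single-kernel REML fits use the decomposition when present, which makes
#' refitting many phenotypes on one kernel (e.g. replicate simulations or
#' cross-validation on a fixed isolate panel) much cheaper.
#'
#' @param x a `pan_kernel`.
#' @return the kernel with an `eigen` element (`values`, `vectors`).
#' @export
kernel_eigen <- function(x) {
  stopifnot(inherits(x, "pan_kernel"))
  if (is.null(x$eigen))
    x$eigen <- eigen(x$K, symmetric = TRUE)
  x
}

#' Write / read a kernel as tab-separated text
#'
#' The matrix goes to `path` as a square TSV with isolate ids as header row
#' and first column; provenance and the scaling constant go to a JSON
#' sidecar at `paste0(path, ".json")`.
#'
#' @param x a `pan_kernel`.
#' @param path output path for the matrix TSV.
#' @export
write_kernel <- function(x, path) {
  write_matrix_tsv(x$K, path)
  jsonlite::write_json(list(provenance = x$provenance, scaling = x$scaling),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  d <- read.delim(path, check.names = FALSE, row.names = 1)
  K <- as.matrix(d)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(provenance = "G", scaling = NA_real_)
  new_pan_kernel(K, meta$provenance, as.numeric(meta$scaling), NULL)
}
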