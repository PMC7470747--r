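# Shared fixtures, all built in code.

iso_ids <- function(n) sprintf("iso%04d", seq_len(n))

# random dosage matrix with controlled allele frequencies
random_genotypes <- function(n, m, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.05, 0.5)
  x <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  dimnames(x) <- list(iso_ids(n), sprintf("m%03d", seq_len(m)))
  genotype_matrix(x)
}

random_orfs <- function(n, m, seed, q = NULL) {
  set.seed(seed)
  if (is.null(q)) q <- runif(m, 0.1, 0.9)
  x <- vapply(q, function(qq) rbinom(n, 1, qq), numeric(n))
  dimnames(x) <- list(iso_ids(n), sprintf("orf%03d", seq_len(m)))
  orf_matrix(x)
}

random_cnos <- function(n, m, seed) {
  set.seed(seed)
  x <- matrix(rpois(n * m, 1.5), n, m,
              dimnames = list(iso_ids(n), sprintf("orf%03d", seq_len(m))))
  cno_matrix(x)
}

# brute-force kernel oracle: elementwise double loop over centered columns
brute_force_kernel <- function(X, centers, denom) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (i in seq_len(ncol(X)))
      acc <- acc + (X[j, i] - centers[i]) * (X[k, i] - centers[i])
    K[j, k] <- acc / denom
  }
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# draw y from the mixed model y ~ N(mu, h2*K + (1-h2)*I) given chol factor
model_true_y <- function(chol_V, ids, mu = 0) {
  setNames(mu + drop(crossprod(chol_V, rnorm(length(ids)))), ids)
}

# a tiny 3-sample VCF written to a temp file; includes one indel and one
# multi-allelic record that readers must skip
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "100", "snpA", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "snpB", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/0", "1/1", sep = "\t"),
    paste("chr1", "300", "indel", "G", "GA", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "400", "multi", "A", "G,T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/2", sep = "\t"))
  writeLines(lines, path)
  path
}
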