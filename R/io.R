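#' Typed predictor matrices
#'
#' The package represents the three layers of pan-genome variation as plain
#' numeric matrices (isolates in rows, markers/ORFs in columns, unique
#' dimnames) carrying a class tag that records which invariants have been
#' validated:
#'
#' * `genotype_matrix` — diploid SNP dosages in \{0, 1, 2\}, `NA` allowed.
#'   The attribute `counted_allele` records, per marker, which allele the
#'   dosage counts (e.g. the ALT allele when read from VCF).
#' * `orf_matrix` — ORF presence/absence in \{0, 1\}, no missing values.
#'   A column of all 1s is a core ORF.
#' * `cno_matrix` — non-negative integer ORF copy numbers. Values of 297 or
#'   more are outside the range observed in the yeast pan-genome data this
#'   toolkit was designed around and trigger a warning (they are kept as-is).
#'
#' @param x numeric matrix, isolates x markers, with unique row and column
#'   names.
#' @param counted_allele optional character vector (one entry per marker)
#'   naming the allele counted by the 0/1/2 code.
#' @return the validated matrix with class tag attached.
#' @name predictor-matrices
NULL

.check_ids <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have isolate row names and marker/ORF column names")
  if (anyDuplicated(rownames(x))) stop("duplicate isolate ids")
  if (anyDuplicated(colnames(x))) stop("duplicate marker/ORF ids")
  invisible(x)
}

#' @rdname predictor-matrices
#' @export
genotype_matrix <- function(x, counted_allele = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .check_ids(x)
  v <- x[!is.na(x)]
  if (length(v) == 0L) stop("genotype matrix has no non-missing calls")
  if (!all(v %in% c(0, 1, 2)))
    stop("genotype values must be 0, 1, 2 or NA")
  if (!is.null(counted_allele)) {
    if (length(counted_allele) != ncol(x))
      stop("counted_allele must have one entry per marker")
    attr(x, "counted_allele") <- counted_allele
  }
  class(x) <- c("genotype_matrix", class(matrix()))
  x
}

#' @rdname predictor-matrices
#' @export
orf_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .check_ids(x)
  if (anyNA(x)) stop("ORF presence/absence matrix cannot contain missing values")
  if (!all(x %in% c(0, 1)))
    stop("ORF presence/absence values must be 0 or 1")
  class(x) <- c("orf_matrix", class(matrix()))
  x
}

#' @rdname predictor-matrices
#' @export
cno_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .check_ids(x)
  if (anyNA(x)) stop("copy-number matrix cannot contain missing values")
  if (any(x < 0) || any(x != round(x)))
    stop("copy numbers must be non-negative integers")
  if (any(x >= 297))
    warning(sum(x >= 297), " copy-number entries are >= 297, outside the ",
            "documented range of the pan-genome data; kept unchanged")
  class(x) <- c("cno_matrix", class(matrix()))
  x
}

#' Read diploid biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only, and codes
#' each genotype as the number of ALT alleles (0, 1, 2; missing calls become
#' `NA`). Multi-allelic records and records whose REF or ALT is not a single
#' base are skipped with a message.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_matrix] (isolates x SNPs) whose `counted_allele`
#'   attribute holds the ALT allele of every retained record.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("no records in VCF: ", path)
  fix <- v@fix
  snp <- vcfR::is.biallelic(v) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped,
            " non-SNP or multi-allelic record(s)")
  if (!any(snp)) stop("no usable biallelic SNP records in VCF: ", path)
  v <- v[snp, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[snp, "ID"]
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])[miss]
  rownames(gt) <- ids
  # dosage = number of ALT alleles; tolerate / and | separators
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[gt_clean == "0/0"] <- 0
  dose[gt_clean %in% c("0/1", "1/0")] <- 1
  dose[gt_clean == "1/1"] <- 2
  genotype_matrix(t(dose), counted_allele = fix[snp, "ALT"])
}

#' Read or write a predictor matrix as tab-separated text
#'
#' The on-disk layout is: header row of marker/ORF ids, first column of
#' isolate ids, `NA` for missing SNP calls. `kind` selects which invariants
#' are enforced on read.
#'
#' @param path file path.
#' @param kind one of `"snp"`, `"orf"`, `"cno"`.
#' @return `read_matrix_tsv`: a typed matrix of the requested kind.
#' @export
read_matrix_tsv <- function(path, kind = c("snp", "orf", "cno")) {
  kind <- match.arg(kind)
  d <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(d)
  switch(kind,
         snp = genotype_matrix(m),
         orf = orf_matrix(m),
         cno = cno_matrix(m))
}

#' @rdname read_matrix_tsv
#' @param x matrix to write (row names = isolate ids).
#' @export
write_matrix_tsv <- function(x, path) {
  d <- data.frame(isolate = rownames(x), unclass(x), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a tab-separated file whose first column holds isolate ids and
#' whose remaining columns are named quantitative traits; `NA` marks missing
#' phenotypes. Isolates with a missing value are dropped per-trait by the
#' analysis functions, never imputed.
#'
#' @param path file path.
#' @return a data.frame with column `isolate` followed by one numeric column
#'   per trait.
#' @export
read_phenotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  names(d)[1] <- "isolate"
  d$isolate <- as.character(d$isolate)
  if (anyDuplicated(d$isolate)) stop("duplicate isolate ids in phenotype table")
  if (ncol(d) < 2L) stop("phenotype table has no trait columns")
  for (j in 2:ncol(d)) d[[j]] <- as.numeric(d[[j]])
  d
}

#' Extract one trait as a named vector
#'
#' Missing phenotypes are dropped, so the result holds exactly the isolates
#' usable for that trait.
#'
#' @param pheno phenotype data.frame as returned by [read_phenotypes].
#' @param trait trait (column) name.
#' @return named numeric vector, names = isolate ids.
#' @export
trait_vector <- function(pheno, trait) {
  if (!trait %in% names(pheno)) stop("no trait '", trait, "' in phenotype table")
  y <- setNames(pheno[[trait]], pheno$isolate)
  y[!is.na(y)]
}
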