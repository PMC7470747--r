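#' Principal component analysis of a predictor matrix
#'
#' Columns are centered internally; scores come from the singular value
#' decomposition of the centered matrix and `variance_explained` gives the
#' fraction of total variance per retained component.
#'
#' @param X numeric matrix, isolates x predictors.
#' @param n_components number of components to keep (default: all nonzero).
#' @return object of class `pan_pca`: `scores` (isolates x components) and
#'   `variance_explained`.
#' @export
pan_pca <- function(X, n_components = NULL) {
  X <- unclass(as.matrix(X))
  if (nrow(X) < 2) stop("PCA needs at least 2 isolates")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve_all <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev^2 > max(pc$sdev^2) * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 variance_explained = ve_all[seq_len(n_components)]),
            class = "pan_pca")
}

#' @export
print.pan_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "isolates,", ncol(x$scores), "components\n")
  cat("variance explained:",
      paste(sprintf("%.3f", head(x$variance_explained, 5)), collapse = " "),
      if (length(x$variance_explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' Pairwise isolate distances from a predictor matrix
#'
#' `count_diff` counts the columns at which two isolates differ (the
#' pairwise gene-distance convention of `ape::dist.gene`); `euclidean` is
#' the ordinary Euclidean distance. On binary presence/absence data the two
#' are related by `euclidean = sqrt(count_diff)`.
#'
#' @param X complete numeric matrix, isolates x columns.
#' @param metric `"count_diff"` (default) or `"euclidean"`.
#' @return symmetric matrix with zero diagonal and isolate dimnames.
#' @export
gene_distance <- function(X, metric = c("count_diff", "euclidean")) {
  metric <- match.arg(metric)
  X <- unclass(as.matrix(X))
  if (anyNA(X)) stop("distance matrix input must be complete")
  D <- switch(metric,
              count_diff = as.matrix(ape::dist.gene(X, method = "pairwise")),
              euclidean = as.matrix(dist(X, method = "euclidean")))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' with a message recording the total clamped length.
#'
#' @param D symmetric distance matrix with isolate dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamped ", sum(neg), " negative branch length(s); ",
            "total deficit ", format(sum(tr$edge.length[neg]), digits = 4))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output path; branch lengths written with 6 decimals.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
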