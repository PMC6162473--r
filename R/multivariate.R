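#' Row-wise z-scoring
#'
#' Centers and scales each row to mean 0 and sample sd 1. Constant rows
#' (zero variance) are dropped with a warning; an all-constant matrix is an
#' error.
#'
#' @param m Numeric matrix (features x samples).
#' @return The z-scored matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 1, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (all(const)) stop("all rows are constant; nothing to z-score")
  if (any(const)) {
    warning("dropping ", sum(const), " constant row(s): ",
            paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (m - rowMeans(m)) / sds
}

#' Hierarchical clustering with Kendall-correlation distance
#'
#' Dissimilarity between two profiles is `1 - tau`, with `tau` the
#' tie-corrected Kendall rank correlation (tau-b): identical rankings give
#' distance 0, exact reversals distance 2. Agglomeration uses average
#' linkage (UPGMA): the distance between clusters is the mean pairwise
#' distance, so merge heights are non-decreasing.
#'
#' @param m Numeric matrix; columns are clustered when `axis = "samples"`
#'   (the default), rows when `axis = "genes"`.
#' @param axis Which margin to cluster.
#' @return Object of class `cluster_tree`: the `stats::hclust` fit plus
#'   metric/linkage labels and the distance matrix.
#' @export
hcluster <- function(m, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  if (axis == "genes") m <- t(m)
  if (ncol(m) < 2) stop("need >= 2 profiles to cluster")
  ndist <- apply(m, 2, function(x) length(unique(x)))
  if (any(ndist < 2))
    stop("Kendall tau undefined for constant profile(s): ",
         paste(colnames(m)[ndist < 2], collapse = ", "))
  d <- 1 - stats::cor(m, method = "kendall")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc, metric = "kendall-distance",
                 linkage = "average", dist = d),
            class = "cluster_tree")
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `cluster_tree`.
#' @param k Number of groups.
#' @return Named integer vector of group labels.
#' @export
cut_tree <- function(tree, k) stats::cutree(tree$hclust, k = k)

#' Export a cluster tree as Newick
#'
#' @param tree A `cluster_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree:", length(x$hclust$labels), "leaves;",
      x$metric, "/", x$linkage, "\n")
  invisible(x)
}

#' Principal component analysis of samples
#'
#' Rows (genes) are z-scored first (centering and unit-scaling each
#' feature), then the processed matrix is decomposed by SVD; per-sample
#' scores and the fraction of variance captured by each component are
#' returned. Variance fractions are non-negative, non-increasing and sum to
#' 1 over all components.
#'
#' @param m Numeric matrix genes x samples, >= 2 samples.
#' @param scale_rows Z-score rows first (default TRUE).
#' @return Object of class `pca_result`: `scores` (samples x components),
#'   `variance_explained`, `sdev`.
#' @export
pca_samples <- function(m, scale_rows = TRUE) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("PCA needs >= 2 samples")
  x <- if (scale_rows) zscore_rows(m) else m - rowMeans(m)
  sv <- svd(x)
  ev <- sv$d^2
  frac <- if (sum(ev) > 0) ev / sum(ev) else ev
  scores <- sv$v %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, variance_explained = frac, sdev = sv$d),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat("pca_result:", nrow(x$scores), "samples; PC1-PC3 explain",
      paste0(paste(ve, collapse = "/"), "% of variance\n"))
  invisible(x)
}

#' Pairwise Spearman correlations among expression profiles
#'
#' Spearman rank correlation (mid-ranks for ties) between every pair of
#' columns, plus the long-format scatter data behind a multiscatter plot.
#'
#' @param profiles Numeric matrix (shared genes x profiles), >= 3 rows.
#' @return List: `r` (symmetric correlation matrix, unit diagonal) and
#'   `data` (long data.frame `gene_id`, `profile_x`, `profile_y`, `x`, `y`).
#' @export
spearman_pairs <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) stop("need >= 3 shared genes")
  r <- stats::cor(profiles, method = "spearman")
  nm <- colnames(profiles)
  combs <- utils::combn(seq_along(nm), 2)
  data <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    data.frame(gene_id = rownames(profiles) %||% seq_len(nrow(profiles)),
               profile_x = nm[i1], profile_y = nm[i2],
               x = profiles[, i1], y = profiles[, i2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(r = r, data = data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
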