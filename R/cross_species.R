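#' Subtype-specific DEG signatures
#'
#' A gene belongs to a subtype's signature when it passes the DEG gates in
#' that subtype and in no other (the exclusive Venn cells, direction
#' ignored). The expression summary carried with each signature is either
#' the mean `log2(FPKM + eps)` over that subtype's tumor samples (default)
#' or the tumor-vs-normal log2 fold change within the subtype.
#'
#' @param partition A `subtype_partition` from [partition_subtypes()].
#' @param expr `expression_set` or FPKM matrix.
#' @param meta Sample metadata if `expr` is a bare matrix.
#' @param eps FPKM pseudocount.
#' @param summary_mode `"tumor-mean"` (default) or `"fold-change"`.
#' @return Named list of signatures, each `list(subtype, genes, profile)`
#'   with `profile` a named numeric over `genes`. Empty signatures trigger a
#'   warning and carry zero-length members.
#' @export
build_signatures <- function(partition, expr, meta = NULL, eps = 0.1,
                             summary_mode = c("tumor-mean", "fold-change")) {
  summary_mode <- match.arg(summary_mode)
  stopifnot(inherits(partition, "subtype_partition"))
  if (inherits(expr, "expression_set")) {
    meta <- expr$meta
    mat <- expr$fpkm
  } else mat <- as.matrix(expr)
  subtypes <- names(partition$passing)
  out <- list()
  for (st in subtypes) {
    others <- unlist(partition$passing[setdiff(subtypes, st)])
    genes <- setdiff(partition$passing[[st]], others)
    if (length(genes) == 0) {
      warning("empty signature for subtype '", st, "'")
      out[[st]] <- list(subtype = st, genes = character(),
                        profile = stats::setNames(numeric(), character()))
      next
    }
    tum <- meta$sample_id[meta$subtype == st & meta$condition == "tumor"]
    prof <- rowMeans(log2(mat[genes, tum, drop = FALSE] + eps))
    if (summary_mode == "fold-change") {
      nor <- meta$sample_id[meta$subtype == st & meta$condition == "normal"]
      prof <- prof - rowMeans(log2(mat[genes, nor, drop = FALSE] + eps))
    }
    out[[st]] <- list(subtype = st, genes = genes, profile = prof)
  }
  out
}

#' Correlate a canine signature with a human subtype panel
#'
#' Maps the signature's genes through a one-to-one ortholog map and computes
#' the Spearman rank correlation (and two-sided p) between the canine
#' expression summary and each human subtype's expression vector over the
#' shared mapped genes. p-values come from exact permutation of the gene
#' labels when n <= 8 and from the t-approximation otherwise.
#'
#' @param signature One element of [build_signatures()] output.
#' @param ortholog_map data.frame `canine_gene_id`, `human_gene_id`
#'   (one-to-one after filtering; duplicated entries are dropped).
#' @param panel Matrix human genes x human subtypes (log-scale expression).
#' @return data.frame `human_subtype`, `r`, `p`, `n`; zero rows (with a
#'   warning giving the reason) when fewer than 3 mapped genes are shared.
#' @export
correlate_with_panel <- function(signature, ortholog_map, panel) {
  dup <- duplicated(ortholog_map$canine_gene_id) |
    duplicated(ortholog_map$human_gene_id)
  ortholog_map <- ortholog_map[!dup, , drop = FALSE]
  hid <- ortholog_map$human_gene_id[match(names(signature$profile),
                                          ortholog_map$canine_gene_id)]
  keep <- !is.na(hid) & hid %in% rownames(panel)
  if (sum(keep) < 3) {
    warning("subtype '", signature$subtype,
            "' skipped: fewer than 3 mapped genes shared with the panel")
    return(data.frame(human_subtype = character(), r = numeric(),
                      p = numeric(), n = integer(), stringsAsFactors = FALSE))
  }
  x <- signature$profile[keep]
  hp <- panel[hid[keep], , drop = FALSE]
  n <- length(x)
  res <- lapply(colnames(hp), function(hs) {
    y <- hp[, hs]
    r <- stats::cor(x, y, method = "spearman")
    p <- .spearman_p(x, y, r, n)
    data.frame(human_subtype = hs, r = r, p = p, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Two-sided p for a Spearman correlation: exact permutation for n <= 8,
# t-approximation with n - 2 df otherwise.
.spearman_p <- function(x, y, r, n) {
  if (is.na(r)) return(NA_real_)
  if (n <= 8) {
    perms <- .all_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    rs <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), n - 2)
  }
}

# All permutations of 1..n as an n! x n matrix (n <= 8 -> at most 40320).
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}
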