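#' Differential expression at the 2-fold / p < 0.01 thresholds
#'
#' Compares tumor against normal samples, either over all animals
#' (`comparison = "overall"`) or restricted to one histological subtype.
#' The fold change is `log2((mean tumor FPKM + eps) / (mean normal FPKM +
#' eps))`; the pseudocount guards against zero denominators. A gene is
#' called a DEG (`passes`) when `|log2fc| >= log2(fc)` (inclusive: a gene at
#' exactly 2-fold passes) and `p < alpha` (strict).
#'
#' Two tests are available on `log2(FPKM + eps)`:
#' \describe{
#'   \item{`"permutation"`}{exact label-permutation test on the difference
#'     of group means — all labelings are enumerated when there are at most
#'     252 (`choose(10, 5)`), otherwise `n_perm` Monte-Carlo draws under the
#'     given seed. Distribution-free and honest at 2-3 samples per group,
#'     where its granularity (>= 2/number of labelings) also means very
#'     small p-values are unreachable.}
#'   \item{`"welch"`}{Welch's unequal-variance t-test, vectorized over
#'     genes.}
#'   \item{`"moderated"`}{limma's moderated t (empirical-Bayes variance
#'     shrinkage across genes, mean-variance trend); the standard and the
#'     most powerful choice when p < 0.01 calls are needed from 2-3
#'     samples per group, and the default for the packaged pipeline.}
#' }
#'
#' @param expr An `expression_set` from [simulate_expression()], or an FPKM
#'   matrix (genes x samples) with `meta` supplied.
#' @param meta Sample metadata (`sample_id`, `condition`, `subtype`);
#'   ignored when `expr` is an `expression_set`.
#' @param comparison `"overall"` or a subtype name.
#' @param test `"permutation"` (default), `"welch"` or `"moderated"`.
#' @param fc Fold-change gate (default 2).
#' @param alpha p-value gate (default 0.01, strict).
#' @param eps FPKM pseudocount (default 0.1).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Seed for Monte-Carlo permutations.
#' @return data.frame of per-gene records: `gene_id`, `comparison`,
#'   `log2fc`, `p_value`, `direction` (`up`/`down`/`none`), `passes`.
#' @export
test_differential <- function(expr, meta = NULL, comparison = "overall",
                              test = c("permutation", "welch", "moderated"),
                              fc = 2, alpha = 0.01, eps = 0.1,
                              n_perm = 2000L, seed = 1L) {
  test <- match.arg(test)
  if (inherits(expr, "expression_set")) {
    meta <- expr$meta
    mat <- expr$fpkm
  } else mat <- as.matrix(expr)
  if (is.null(meta)) stop("sample metadata required")
  stopifnot(all(colnames(mat) %in% meta$sample_id))
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  keep <- if (comparison == "overall") rep(TRUE, nrow(meta)) else
    meta$subtype == comparison
  sub <- mat[, keep, drop = FALSE]
  cond <- meta$condition[keep]
  nt <- sum(cond == "tumor"); nn <- sum(cond == "normal")
  if (nt < 2 || nn < 2)
    stop("comparison '", comparison, "' needs >= 2 samples per group (got ",
         nt, " tumor, ", nn, " normal)")

  mt <- rowMeans(sub[, cond == "tumor", drop = FALSE])
  mn <- rowMeans(sub[, cond == "normal", drop = FALSE])
  log2fc <- log2((mt + eps) / (mn + eps))

  y <- log2(sub + eps)
  p <- switch(test,
    permutation = .perm_p(y, cond == "tumor", n_perm, seed),
    welch = .welch_p(y, cond == "tumor"),
    moderated = .moderated_p(y, cond == "tumor"))

  passes <- abs(log2fc) >= log2(fc) & p < alpha
  direction <- ifelse(passes, ifelse(log2fc > 0, "up", "down"), "none")
  data.frame(gene_id = rownames(mat), comparison = comparison,
             log2fc = log2fc, p_value = p, direction = direction,
             passes = passes, row.names = NULL, stringsAsFactors = FALSE)
}

# Exact / Monte-Carlo permutation p on the difference of group means.
.perm_p <- function(y, is_t, n_perm, seed) {
  n <- ncol(y); k <- sum(is_t)
  w_obs <- ifelse(is_t, 1 / k, -1 / (n - k))
  obs <- drop(y %*% w_obs)
  ncomb <- choose(n, k)
  if (ncomb <= 252) {
    combs <- utils::combn(n, k)
    W <- matrix(-1 / (n - k), nrow = n, ncol = ncol(combs))
    for (j in seq_len(ncol(combs))) W[combs[, j], j] <- 1 / k
    stats_m <- y %*% W                       # genes x labelings
    rowMeans(abs(stats_m) >= abs(obs) - 1e-12)
  } else {
    set.seed(seed)
    hit <- rep(1L, nrow(y))                  # observed labeling counts itself
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, k)
      w <- rep(-1 / (n - k), n); w[idx] <- 1 / k
      hit <- hit + (abs(drop(y %*% w)) >= abs(obs) - 1e-12)
    }
    hit / (n_perm + 1)
  }
}

# Moderated t via limma: empirical-Bayes variance shrinkage with a
# mean-variance trend, two-group design.
.moderated_p <- function(y, is_t) {
  design <- cbind(intercept = 1, tumor = as.numeric(is_t))
  fit <- limma::lmFit(y, design)
  eb <- limma::eBayes(fit, trend = TRUE)
  p <- eb$p.value[, "tumor"]
  p[is.na(p)] <- 1
  unname(p)
}

# Vectorized Welch t-test on rows of y.
.welch_p <- function(y, is_t) {
  a <- y[, is_t, drop = FALSE]; b <- y[, !is_t, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: both groups constant
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Partition DEGs across the three subtypes (Venn cells)
#'
#' Set algebra over the passing gene ids of the three per-subtype DEG
#' calls, split by direction. All seven Venn cells are emitted per
#' direction, plus direction-agnostic subtype-specific sets used for the
#' cross-species signatures.
#'
#' @param records_list Named list (complex/ductal/simple) of record
#'   data.frames from [test_differential()].
#' @return Object of class `subtype_partition`: for each direction
#'   (`up`, `down`) the per-subtype sets and all 7 Venn cells; `passing`
#'   holds per-subtype direction-agnostic DEG sets.
#' @export
partition_subtypes <- function(records_list) {
  stopifnot(length(records_list) == 3, !is.null(names(records_list)))
  get_set <- function(df, dir) sort(df$gene_id[df$passes & df$direction == dir])
  out <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(records_list, get_set, dir = dir)
    out[[dir]] <- list(sets = sets, cells = venn_cells(sets))
  }
  out$passing <- lapply(records_list, function(df) sort(df$gene_id[df$passes]))
  structure(out, class = "subtype_partition")
}

#' Venn cells of three sets
#'
#' @param sets Named list of three character vectors.
#' @return Named list of the 7 exclusive Venn cells: the three
#'   single-set-only cells, three pairwise-only cells and the three-way
#'   intersection.
#' @export
venn_cells <- function(sets) {
  stopifnot(length(sets) == 3)
  nm <- names(sets)
  A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
  cells <- list(
    setdiff(A, union(B, C)),
    setdiff(B, union(A, C)),
    setdiff(C, union(A, B)),
    setdiff(intersect(A, B), C),
    setdiff(intersect(A, C), B),
    setdiff(intersect(B, C), A),
    Reduce(intersect, sets))
  names(cells) <- c(nm, paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
  lapply(cells, sort)
}

#' @export
print.subtype_partition <- function(x, ...) {
  for (dir in c("up", "down")) {
    cat(dir, "cells:",
        paste(sprintf("%s=%d", names(x[[dir]]$cells),
                      lengths(x[[dir]]$cells)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Top differentially expressed genes
#'
#' The `n` strongest up- and down-regulated passing genes per comparison,
#' ranked by signed log2 fold change with ties broken lexicographically by
#' gene id, reported with `-log10(p)`.
#'
#' @param records Record data.frame(s) from [test_differential()] (rbind
#'   multiple comparisons freely).
#' @param n Genes per direction (default 5).
#' @param passing_only Restrict to passing DEGs (default TRUE).
#' @return data.frame `comparison`, `direction`, `gene_id`, `log2fc`,
#'   `neg_log10_p`.
#' @export
summarize_degs <- function(records, n = 5, passing_only = TRUE) {
  if (nrow(records) == 0) stop("no records to summarize")
  if (passing_only) records <- records[records$passes, , drop = FALSE]
  out <- list()
  for (cmp in unique(records$comparison)) {
    r <- records[records$comparison == cmp, , drop = FALSE]
    up <- r[r$log2fc > 0, , drop = FALSE]
    up <- up[order(-up$log2fc, up$gene_id), , drop = FALSE]
    dn <- r[r$log2fc < 0, , drop = FALSE]
    dn <- dn[order(dn$log2fc, dn$gene_id), , drop = FALSE]
    pick <- rbind(
      if (nrow(up)) cbind(up[seq_len(min(n, nrow(up))), ], direction2 = "up"),
      if (nrow(dn)) cbind(dn[seq_len(min(n, nrow(dn))), ], direction2 = "down"))
    if (is.null(pick) || nrow(pick) == 0) next
    out[[cmp]] <- data.frame(
      comparison = cmp, direction = pick$direction2, gene_id = pick$gene_id,
      log2fc = pick$log2fc, neg_log10_p = -log10(pick$p_value),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(comparison = character(), direction = character(),
               gene_id = character(), log2fc = numeric(),
               neg_log10_p = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
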