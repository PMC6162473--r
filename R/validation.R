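#' qPCR relative quantification by the 2^-ddCt method
#'
#' For each record, `dCt = ct_target - ct_reference` normalizes the target
#' gene to the reference (housekeeping) gene; `ddCt` then normalizes to a
#' calibrator — by default the mean `dCt` of the normal-condition samples
#' of the same gene — and relative expression is `2^-ddCt`, so a tumor
#' sample expressing the target 16-fold over the normal calibrator has
#' `ddCt = -4`.
#'
#' @param records data.frame with `sample_id`, `condition`, `gene`,
#'   `ct_target`, `ct_reference` (and `pair_id` for the paired calibrator).
#' @param calibrator `"mean-normal"` (default) calibrates each gene against
#'   the mean normal dCt; `"paired"` calibrates each tumor sample against
#'   its own pair's normal dCt (requires `pair_id`).
#' @return `records` with added `dct`, `ddct`, `rel_expr` columns.
#' @export
ddct <- function(records, calibrator = c("mean-normal", "paired")) {
  calibrator <- match.arg(calibrator)
  need <- c("sample_id", "condition", "gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(records)))
  bad <- !is.finite(records$ct_target) | !is.finite(records$ct_reference)
  if (any(bad))
    stop("missing or non-finite Ct for sample(s): ",
         paste(records$sample_id[bad], collapse = ", "))
  out <- records
  out$dct <- out$ct_target - out$ct_reference
  out$ddct <- NA_real_
  for (g in unique(out$gene)) {
    sel <- out$gene == g
    if (calibrator == "mean-normal") {
      normals <- out$dct[sel & out$condition == "normal"]
      if (length(normals) < 1) stop("no normal sample for gene ", g)
      out$ddct[sel] <- out$dct[sel] - mean(normals)
    } else {
      if (is.null(out$pair_id)) stop("paired calibrator requires 'pair_id'")
      for (p in unique(out$pair_id[sel])) {
        ps <- sel & out$pair_id == p
        cal <- out$dct[ps & out$condition == "normal"]
        if (length(cal) != 1) stop("pair ", p, " of gene ", g,
                                   " lacks a unique normal sample")
        out$ddct[ps] <- out$dct[ps] - cal
      }
    }
  }
  out$rel_expr <- 2^(-out$ddct)
  out
}

# Null distribution of the rank-sum of group 1 under random labeling,
# counted by subset-sum dynamic programming over the ranks 1..n1+n2:
# ways[j, s] = number of j-subsets of {1..N} with rank sum s. Exact for
# tie-free data; counts are integers held in doubles (exact far beyond
# n1 = n2 = 12, where choose(24,12) ~ 2.7e6).
.mw_null_counts <- function(n1, n2) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1):N)
  ways <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (i in seq_len(N)) {
    for (j in min(i, n1):1) {
      src <- ways[j, ]
      shifted <- c(rep(0, i), src[seq_len(smax + 1 - i)])
      ways[j + 1, ] <- ways[j + 1, ] + shifted
    }
  }
  counts <- ways[n1 + 1, ]
  # index s+1 holds rank-sum s; convert to U = s - n1(n1+1)/2
  offset <- n1 * (n1 + 1) / 2
  u_counts <- counts[(offset + 1):(smax + 1)]
  names(u_counts) <- 0:(n1 * n2)
  u_counts
}

#' Exact null distribution and p-value of the Mann-Whitney U statistic
#'
#' `mw_null_distribution()` returns the exact probability mass of U for
#' given group sizes (tie-free), computed by dynamic programming over rank
#' sums. `mw_u_pvalue()` evaluates the two-sided p at an observed U in
#' min-orientation: twice the lower tail `P(U <= u)` (the null is
#' symmetric), capped at 1.
#'
#' @param u Observed U (min of the two orientations).
#' @param n1,n2 Group sizes.
#' @return `mw_null_distribution`: named numeric of `P(U = u)` for
#'   `u = 0..n1*n2`. `mw_u_pvalue`: the two-sided p-value.
#' @export
mw_null_distribution <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  cnt <- .mw_null_counts(n1, n2)
  cnt / sum(cnt)
}

#' @rdname mw_null_distribution
#' @export
mw_u_pvalue <- function(u, n1, n2) {
  if (u < 0 || u > n1 * n2) stop("U out of range [0, n1*n2]")
  pm <- mw_null_distribution(n1, n2)
  min(1, 2 * sum(pm[seq_len(floor(u) + 1)]))
}

#' Exact Mann-Whitney U test
#'
#' U is computed from mid-ranks and reported in min-orientation
#' (`U = min(U1, U2)`, so `0 <= U <= n1*n2/2`). For tie-free data the
#' two-sided p comes from the exact DP-enumerated null distribution of U;
#' with ties the exact tie-free null no longer applies and the p-value is
#' estimated by Monte-Carlo label permutation under a fixed seed.
#'
#' @param x,y Numeric vectors (the two groups), non-empty.
#' @param n_mc Monte-Carlo permutations used when ties are present.
#' @param seed Seed for the Monte-Carlo branch.
#' @return List of class `mw_test`: `U`, `n1`, `n2`, `p_two_sided`, `auc`
#'   (via [auc_from_u()]), `method`.
#' @export
mann_whitney_exact <- function(x, y, n_mc = 10000L, seed = 1L) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)  # mid-ranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  has_ties <- anyDuplicated(all_v) > 0
  if (!has_ties) {
    p <- mw_u_pvalue(u, n1, n2)
    method <- "exact"
  } else {
    set.seed(seed)
    hit <- 1L
    for (b in seq_len(n_mc)) {
      rp <- r[sample.int(n1 + n2)]
      u1p <- sum(rp[seq_len(n1)]) - n1 * (n1 + 1) / 2
      up <- min(u1p, n1 * n2 - u1p)
      if (up <= u + 1e-9) hit <- hit + 1L
    }
    p <- min(1, hit / (n_mc + 1))
    method <- "monte-carlo (ties)"
  }
  structure(list(U = u, n1 = n1, n2 = n2, p_two_sided = p,
                 auc = auc_from_u(u, n1, n2), method = method),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d/%d), p = %.4g [%s]; AUC = %.4f\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method, x$auc))
  invisible(x)
}

#' AUC from the Mann-Whitney U statistic
#'
#' The empirical ROC area equals `1 - U/(n1*n2)` when U is reported in
#' min-orientation, which makes the returned AUC direction-agnostic and
#' at least 0.5.
#'
#' @param u U statistic, in `[0, n1*n2]`.
#' @param n1,n2 Group sizes.
#' @return The AUC.
#' @export
auc_from_u <- function(u, n1, n2) {
  if (u < 0 || u > n1 * n2) stop("U out of range [0, n1*n2]")
  1 - u / (n1 * n2)
}

#' Empirical ROC curve with Hanley-McNeil confidence interval
#'
#' Computes the empirical ROC over all thresholds of `values` (ties grouped
#' so the curve is a step/diagonal path from (0,0) to (1,1)), the
#' tie-corrected rank-statistic AUC in direction-agnostic orientation
#' (>= 0.5), and a 95 percent CI from the Hanley-McNeil variance formula.
#'
#' @param values Numeric scores.
#' @param labels Two-level class labels (the positive class is oriented so
#'   AUC >= 0.5).
#' @return List of class `roc_result`: `points` (data.frame `fpr`, `tpr`,
#'   `threshold`), `auc`, `ci` (length-2), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("labels must contain exactly two classes")
  labels <- droplevels(labels)
  pos <- levels(labels)[2]
  is_pos <- labels == pos
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  r <- rank(values)
  a <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)  # tie-corrected
  flip <- a < 0.5
  if (flip) {
    a <- 1 - a
    values <- -values
  }
  ord <- order(values, decreasing = TRUE)
  v <- values[ord]; yp <- is_pos[ord]
  thr <- unique(v)
  tpr <- c(0, vapply(thr, function(t) sum(yp & v >= t) / n1, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(!yp & v >= t) / n2, numeric(1)))
  pts <- data.frame(fpr = fpr, tpr = tpr,
                    threshold = c(Inf, thr), row.names = NULL)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
             (n1 * n2))
  ci <- pmin(1, pmax(0, a + c(-1, 1) * stats::qnorm(0.975) * se))
  structure(list(points = pts, auc = a, ci = ci, n_pos = n1, n_neg = n2,
                 flipped = flip),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (95%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' qPCR validation statistics for a set of target genes
#'
#' Runs the full validation chain on a qPCR Ct table: 2^-ddCt relative
#' expression per sample, exact Mann-Whitney U comparing tumor vs normal
#' relative expression per gene, and the ROC/AUC with Hanley-McNeil CI.
#'
#' @param records qPCR table as from [simulate_qpcr()].
#' @param calibrator Passed to [ddct()].
#' @return data.frame one row per gene: `gene`, `U`, `n1`, `n2`,
#'   `p_two_sided`, `auc`, `auc_lo`, `auc_hi`.
#' @export
validate_qpcr <- function(records, calibrator = "mean-normal") {
  rel <- ddct(records, calibrator = calibrator)
  out <- lapply(unique(rel$gene), function(g) {
    rg <- rel[rel$gene == g, ]
    tum <- rg$rel_expr[rg$condition == "tumor"]
    nor <- rg$rel_expr[rg$condition == "normal"]
    mw <- mann_whitney_exact(tum, nor)
    roc <- roc_curve(rg$rel_expr, rg$condition == "tumor")
    data.frame(gene = g, U = mw$U, n1 = mw$n1, n2 = mw$n2,
               p_two_sided = mw$p_two_sided, auc = roc$auc,
               auc_lo = roc$ci[1], auc_hi = roc$ci[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
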