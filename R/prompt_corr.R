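#' PROMPT-region fold changes
#'
#' Converts a PROMPT-window count matrix to per-region tumor-vs-normal log2
#' fold changes. Counts are normalized to fragments per million mapped
#' fragments before averaging so that library-size imbalance between
#' conditions cancels; the raw mean count is retained for the low-count
#' flag downstream.
#'
#' @param prompt_counts Regions x samples count matrix (rownames = gene ids
#'   of the parent genes).
#' @param meta Sample metadata (`sample_id`, `condition`).
#' @param eps Pseudocount on the per-million scale (default 0.1).
#' @param lib_sizes Mapped fragments per sample; defaults to the column
#'   sums of `prompt_counts`.
#' @return data.frame `gene_id`, `prompt_log2fc`, `prompt_mean_count`.
#' @export
prompt_fold_changes <- function(prompt_counts, meta, eps = 0.1,
                                lib_sizes = colSums(prompt_counts)) {
  m <- as.matrix(prompt_counts)
  stopifnot(all(colnames(m) %in% meta$sample_id))
  if (any(lib_sizes <= 0)) {
    # samples with no fragments at all cannot be normalized; treat as size 1
    lib_sizes[lib_sizes <= 0] <- 1
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (!any(meta$condition == "tumor") || !any(meta$condition == "normal"))
    stop("both tumor and normal samples are required")
  cpm <- sweep(m, 2, lib_sizes, "/") * 1e6
  mt <- rowMeans(cpm[, meta$condition == "tumor", drop = FALSE])
  mn <- rowMeans(cpm[, meta$condition == "normal", drop = FALSE])
  data.frame(gene_id = rownames(m),
             prompt_log2fc = log2((mt + eps) / (mn + eps)),
             prompt_mean_count = rowMeans(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify gene-PROMPT pairs by fold-change concordance
#'
#' Joins DEG records with PROMPT-region fold changes and applies the dual
#' threshold: a pair is classified only when the gene passes its DEG gates
#' (p < `alpha`, |log2fc| >= log2(`fc`)) *and* the PROMPT change clears the
#' same fold gate. Classified pairs are `positive` when the gene and PROMPT
#' fold changes share a sign and `negative` otherwise; everything else is
#' `excluded`. With a single fold change per gene and per region, per-pair
#' concordance of sign is the operative notion of correlation; an overall
#' Pearson correlation of (gene, PROMPT) log2 fold changes is computed
#' across the positive-class pairs (negatives being low-count-suspect), and
#' across all classified pairs as a secondary figure.
#'
#' @param deg_records Records from [test_differential()] (one comparison).
#' @param prompt_fcs From [prompt_fold_changes()].
#' @param min_mean_count Pairs with mean raw window count below this are
#'   flagged `low_count` (default 5 fragments).
#' @param fc,alpha Gates shared with the DEG call (defaults 2 and 0.01).
#' @return List of class `prompt_pairs`: `pairs` (data.frame `gene_id`,
#'   `gene_log2fc`, `gene_p`, `prompt_log2fc`, `prompt_mean_count`, `class`,
#'   `low_count_flag`) and `summary` (`n_positive`, `n_negative`,
#'   `n_excluded`, `overall_r`, `overall_r_all`; correlations are `NA` when
#'   fewer than 3 pairs support them).
#' @export
classify_pairs <- function(deg_records, prompt_fcs, min_mean_count = 5,
                           fc = 2, alpha = 0.01) {
  joined <- merge(
    deg_records[, c("gene_id", "log2fc", "p_value")],
    prompt_fcs, by = "gene_id")
  names(joined)[names(joined) == "log2fc"] <- "gene_log2fc"
  names(joined)[names(joined) == "p_value"] <- "gene_p"
  gene_pass <- abs(joined$gene_log2fc) >= log2(fc) & joined$gene_p < alpha
  prompt_pass <- abs(joined$prompt_log2fc) >= log2(fc)
  concord <- sign(joined$gene_log2fc) == sign(joined$prompt_log2fc)
  joined$class <- ifelse(gene_pass & prompt_pass,
                         ifelse(concord, "positive", "negative"),
                         "excluded")
  joined$low_count_flag <- joined$prompt_mean_count < min_mean_count
  joined <- joined[order(joined$gene_id), ]
  rownames(joined) <- NULL

  pos <- joined[joined$class == "positive", ]
  cls <- joined[joined$class != "excluded", ]
  r_of <- function(df) if (nrow(df) >= 3)
    stats::cor(df$gene_log2fc, df$prompt_log2fc) else NA_real_
  summary <- list(n_positive = sum(joined$class == "positive"),
                  n_negative = sum(joined$class == "negative"),
                  n_excluded = sum(joined$class == "excluded"),
                  overall_r = r_of(pos),
                  overall_r_all = r_of(cls))
  structure(list(pairs = joined, summary = summary), class = "prompt_pairs")
}

#' @export
print.prompt_pairs <- function(x, ...) {
  s <- x$summary
  cat(sprintf("prompt_pairs: %d positive, %d negative, %d excluded; overall r (positive) = %s\n",
              s$n_positive, s$n_negative, s$n_excluded,
              ifelse(is.na(s$overall_r), "NA", format(s$overall_r, digits = 4))))
  invisible(x)
}
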