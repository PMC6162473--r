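#!/usr/bin/env Rscript

# Stage 7 -- gene-PROMPT fold-change concordance.
#
# Joins the overall DEG calls with PROMPT-window fold changes, applies the
# dual gates (gene: p < 0.01 and |fc| >= 2; window: |fc| >= 2), classifies
# pairs by sign concordance, and reports the overall correlation of gene
# and window fold changes across the positive pairs.

suppressPackageStartupMessages(library(mgcprompt))

counts <- read_matrix_tsv("results/quantify/prompt_counts.tsv")
meta <- read_tsv("results/data/sample_meta.tsv")
deg <- read_tsv("results/deg/deg_overall.tsv")
planted <- read_tsv("results/data/planted_prompt_pairs.tsv")
dir.create("results/prompt_corr", showWarnings = FALSE, recursive = TRUE)

pfc <- prompt_fold_changes(counts, meta)
pairs <- classify_pairs(deg, pfc, min_mean_count = 5)
write_tsv(pairs$pairs, "results/prompt_corr/prompt_pairs.tsv")
jsonlite::write_json(pairs$summary, "results/prompt_corr/summary.json",
                     auto_unbox = TRUE, digits = NA, na = "null")

s <- pairs$summary
cat(sprintf("%d positive and %d negative gene-PROMPT pairs (%d excluded)\n",
            s$n_positive, s$n_negative, s$n_excluded))
cat("overall r over positive pairs:",
    ifelse(is.na(s$overall_r), "NA", sprintf("%.3f", s$overall_r)), "\n")
got <- pairs$pairs$gene_id[pairs$pairs$class == "positive"]
cat("planted positives recovered:",
    sum(planted$gene_id[planted$class == "positive"] %in% got), "/",
    sum(planted$class == "positive"), "\n")
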