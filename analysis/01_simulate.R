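#!/usr/bin/env Rscript

# Stage 1 -- generate the synthetic study inputs.
#
# Emulates the paired design under analysis: 8 dogs (3 complex, 3 ductal,
# 2 simple histological subtypes), one tumor and one matched normal sample
# each, with planted overall and subtype-specific expression changes of at
# least 2-fold, PROMPT signal planted upstream of a subset of up-regulated
# genes, and a 12-pair qPCR panel. All downstream stages read only the
# files written here.

suppressPackageStartupMessages(library(mgcprompt))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = 101)

models <- generate_annotation(cfg, gtf_path = file.path(outdir, "annotation.gtf"))
cat("annotation:", length(models$genes), "genes on",
    length(GenomeInfoDb::seqlevels(models$genes)), "chromosomes\n")

expr <- simulate_expression(models, cfg)
write_tsv(expr$counts, file.path(outdir, "counts.tsv"))
write_tsv(expr$fpkm, file.path(outdir, "fpkm.tsv"))
write_tsv(data.frame(gene_id = names(expr$lengths), length = expr$lengths),
          file.path(outdir, "gene_lengths.tsv"))
write_tsv(expr$meta, file.path(outdir, "sample_meta.tsv"))
write_tsv(expr$truth, file.path(outdir, "truth_degs.tsv"))
cat("expression:", nrow(expr$counts), "genes x", ncol(expr$counts),
    "samples;", nrow(expr$truth), "planted effects\n")

regions <- build_prompt_regions(models, window = 1500)
planted <- planted_prompt_pairs(expr$truth, regions, cfg)
frags <- simulate_prompt_fragments(models, regions, planted, expr$meta, cfg)
write_fragments_bed(frags, file.path(outdir, "prompt_fragments.bed"))
write_tsv(planted, file.path(outdir, "planted_prompt_pairs.tsv"))
cat("fragments:", length(frags), "stranded PROMPT-window fragments;",
    nrow(planted), "planted gene-PROMPT pairs\n")

qpcr <- simulate_qpcr(cfg)
write_tsv(qpcr, file.path(outdir, "qpcr_ct.tsv"))
cat("qPCR:", cfg$qpcr_n_pairs, "tumor/normal pairs x",
    length(unique(qpcr$gene)), "genes\n")
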