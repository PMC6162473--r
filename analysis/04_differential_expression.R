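#!/usr/bin/env Rscript

# Stage 4 -- DEG calling and subtype partitioning.
#
# Four comparisons (overall plus each histological subtype) at the
# |fold change| >= 2, p < 0.01 thresholds, with the moderated t-test (the
# appropriate choice at 2-3 animals per subtype). DEGs are partitioned
# across subtypes into Venn cells, split by direction.

suppressPackageStartupMessages(library(mgcprompt))

fpkm <- read_matrix_tsv("results/data/fpkm.tsv")
meta <- read_tsv("results/data/sample_meta.tsv")
truth <- read_tsv("results/data/truth_degs.tsv")
dir.create("results/deg", showWarnings = FALSE, recursive = TRUE)

comparisons <- c("overall", "complex", "ductal", "simple")
degs <- lapply(comparisons, function(cmp)
  test_differential(fpkm, meta, comparison = cmp, test = "moderated"))
names(degs) <- comparisons

for (cmp in comparisons) {
  write_tsv(degs[[cmp]], file.path("results/deg", paste0("deg_", cmp, ".tsv")))
  d <- degs[[cmp]]
  truth_cmp <- truth$gene_id[truth$subtype %in%
                             if (cmp == "overall") "overall" else c(cmp, "overall")]
  cat(sprintf("%-8s %3d DEGs (%d up / %d down); %d/%d planted recovered\n",
              cmp, sum(d$passes), sum(d$direction == "up"),
              sum(d$direction == "down"),
              sum(truth_cmp %in% d$gene_id[d$passes]), length(truth_cmp)))
}

part <- partition_subtypes(degs[c("complex", "ductal", "simple")])
venn <- do.call(rbind, lapply(c("up", "down"), function(dir)
  data.frame(direction = dir, cell = names(part[[dir]]$cells),
             n = lengths(part[[dir]]$cells), stringsAsFactors = FALSE)))
write_tsv(venn, "results/deg/venn_cells.tsv")
shared <- length(part$up$cells[["complex&ductal&simple"]]) +
  length(part$down$cells[["complex&ductal&simple"]])
cat("genes shared by all three subtypes:", shared, "\n")

top <- summarize_degs(do.call(rbind, degs), n = 5)
write_tsv(top, "results/deg/top_degs.tsv")
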