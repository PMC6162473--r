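#!/usr/bin/env Rscript

# Stage 5 -- clustering, PCA, and subtype correlation structure.
#
# Samples are clustered on z-scored DEG expression with Kendall-correlation
# distance and average linkage; PCA reports per-component variance
# fractions; subtype DEG profiles are compared by Spearman correlation.

suppressPackageStartupMessages(library(mgcprompt))

fpkm <- read_matrix_tsv("results/data/fpkm.tsv")
meta <- read_tsv("results/data/sample_meta.tsv")
deg <- read_tsv("results/deg/deg_overall.tsv")
dir.create("results/multivariate", showWarnings = FALSE, recursive = TRUE)

deg_genes <- deg$gene_id[deg$passes]
cat(length(deg_genes), "overall DEGs enter the multivariate analysis\n")
sub <- fpkm[deg_genes, , drop = FALSE]

tree <- hcluster(suppressWarnings(zscore_rows(sub)), axis = "samples")
export_newick(tree, "results/multivariate/cluster_samples.nwk")
k2 <- cut_tree(tree, 2)
agree <- max(mean((k2 == 1) == (meta$condition[match(names(k2), meta$sample_id)]
                                == "tumor")),
             mean((k2 == 2) == (meta$condition[match(names(k2), meta$sample_id)]
                                == "tumor")))
cat("cutting the dendrogram at k = 2 matches tumor/normal for",
    sprintf("%.0f%%", 100 * agree), "of samples\n")

pc <- pca_samples(sub)
write_tsv(data.frame(sample_id = rownames(pc$scores),
                     pc$scores[, 1:3, drop = FALSE]),
          "results/multivariate/pca_scores.tsv")
write_tsv(data.frame(component = seq_along(pc$variance_explained),
                     variance_explained = pc$variance_explained),
          "results/multivariate/pca_variance.tsv")
cat(sprintf("PC1/PC2/PC3 explain %.1f%% / %.1f%% / %.1f%% of variance\n",
            100 * pc$variance_explained[1], 100 * pc$variance_explained[2],
            100 * pc$variance_explained[3]))

subs <- c("complex", "ductal", "simple")
union_genes <- sort(unique(unlist(lapply(subs, function(s) {
  d <- read_tsv(file.path("results/deg", paste0("deg_", s, ".tsv")))
  d$gene_id[d$passes]
}))))
prof <- vapply(subs, function(s) {
  tum <- meta$sample_id[meta$subtype == s & meta$condition == "tumor"]
  rowMeans(log2(fpkm[union_genes, tum, drop = FALSE] + 0.1))
}, numeric(length(union_genes)))
sp <- spearman_pairs(prof)
write_tsv(sp$r, "results/multivariate/subtype_spearman.tsv")
cat("subtype profile Spearman correlations:",
    paste(sprintf("%s-%s %.2f", subs[c(1, 1, 2)], subs[c(2, 3, 3)],
                  sp$r[cbind(c(1, 1, 2), c(2, 3, 3))]), collapse = ", "), "\n")
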