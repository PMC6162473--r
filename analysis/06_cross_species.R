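#!/usr/bin/env Rscript

# Stage 6 -- cross-species subtype correlation.
#
# Subtype-specific DEG signatures (exclusive Venn cells) are mapped through
# a one-to-one ortholog table and correlated (Spearman) against a
# four-subtype human breast-cancer expression panel. The synthetic panel
# plants one matched human subtype (HER2) as a noisy monotone transform of
# the first canine signature, so the analysis should single it out.

suppressPackageStartupMessages(library(mgcprompt))

fpkm <- read_matrix_tsv("results/data/fpkm.tsv")
meta <- read_tsv("results/data/sample_meta.tsv")
degs <- lapply(c("complex", "ductal", "simple"), function(s)
  read_tsv(file.path("results/deg", paste0("deg_", s, ".tsv"))))
names(degs) <- c("complex", "ductal", "simple")
dir.create("results/cross_species", showWarnings = FALSE, recursive = TRUE)

part <- partition_subtypes(degs)
sigs <- suppressWarnings(build_signatures(part, fpkm, meta))
for (s in names(sigs))
  cat("signature", s, ":", length(sigs[[s]]$genes), "subtype-specific genes\n")

nonempty <- names(sigs)[vapply(sigs, function(x) length(x$genes) >= 3,
                               logical(1))]
omap <- simulate_ortholog_map(rownames(fpkm))
panel <- simulate_human_panel(sigs[[nonempty[1]]]$profile, omap,
                              matched_subtype = "HER2", seed = 101)
write_tsv(omap, "results/cross_species/ortholog_map.tsv")
write_tsv(panel, "results/cross_species/human_panel.tsv")

res <- do.call(rbind, lapply(nonempty, function(s) {
  r <- suppressWarnings(correlate_with_panel(sigs[[s]], omap, panel))
  if (nrow(r)) cbind(canine_subtype = s, r) else NULL
}))
write_tsv(res, "results/cross_species/correlations.tsv")
best <- res[res$canine_subtype == nonempty[1], ]
cat("planted match for", nonempty[1], "-> argmax r is",
    best$human_subtype[which.max(best$r)],
    sprintf("(r = %.3f, p = %.2g, n = %d)", max(best$r),
            best$p[which.max(best$r)], best$n[1]), "\n")
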