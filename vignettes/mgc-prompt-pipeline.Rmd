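---
title: "Promoter-upstream transcription and differential expression in canine mammary carcinoma: methods"
author: "mgcprompt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-upstream transcription and differential expression in canine mammary carcinoma: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures, the parameters that matter, the numerical conventions, and what
the synthetic data can and cannot certify about real data.

## The analysis in one paragraph

Eight dogs with mammary gland carcinoma (MGC) — three complex-, three
ductal- and two simple-subtype — each contribute a tumor and a matched
adjacent-normal RNA-seq library. Genes are quantified as FPKM; genes with
|fold change| of at least 2 and p < 0.01 in a comparison are differentially
expressed genes (DEGs), called overall and per subtype, then partitioned
across subtypes (Venn cells). Expression structure is examined by
hierarchical clustering with Kendall-correlation distance, PCA, and Spearman
multiscatter. Subtype-specific DEG signatures are correlated with a human
breast-cancer subtype panel through orthologs. Separately, every gene's
promoter-upstream window (TSS to −1500 bp, cleansed of other genes'
transcript spans) is quantified from stranded fragments; gene and window
fold changes are jointly gated and classified by sign concordance into
positive/negative gene–PROMPT pairs. Finally, selected genes are validated
by qPCR: 2^−ΔΔCt relative expression, exact Mann–Whitney U, and ROC/AUC.

## Coordinate and format conventions

Internally everything is a Bioconductor `GRanges`: 1-based, closed
intervals. GTF input/output is 1-based inclusive (Ensembl dialect, with
`#!sequence-region` header directives carrying chromosome lengths so files
round-trip); BED input/output is 0-based half-open, as the format requires
(`rtracklayer` performs the shift). A single-exon gene written as GTF
`[1001, 2000]` on `+` therefore has TSS 1001; on `−` its TSS is 2000.

## PROMPT regions

The nominal window is the 1500 bp immediately upstream of the TSS in the
gene's own orientation, clipped at chromosome bounds. Window size is a
parameter (`window`, bp); 1500 is the default because promoter-upstream
transcription concentrates within roughly a kilobase upstream of active
TSSs and the analysis this package implements used that extent.

"Shared with other genes" is interpreted as *any overlap with another
gene's transcript span, on either strand* (default
`exclusion = "both-strands"`): since window counting collects all fragments
regardless of strand, a window base inside any neighbor's transcript cannot
be attributed to promoter-upstream transcription. `"same-strand"` and
`"exons-only"` policies are provided for sensitivity analysis. A gene whose
window is entirely consumed is retained with effective length 0 and
flagged, not dropped, so bookkeeping stays conservative. For
multi-transcript genes the TSS is the 5′-most start on the gene's strand
(here, the gene span's 5′ end). Regions are built per gene; subtraction is
ordinary interval algebra (IRanges), and a per-base brute-force membership
oracle in the test suite certifies it on random annotations.

## Quantification

A fragment counts toward a feature when it overlaps it by at least 1 bp
(`min_overlap` exposes stricter rules) and satisfies the strand mode:
`same` for gene counting of a stranded library, `ignore` (default) for
PROMPT windows, since all upstream signal is collected. A fragment
overlapping several features counts in each (PROMPT windows already exclude
other genes' spans, so structural double counting is confined to
overlapping windows of divergent gene pairs); a fragment spanning two
intervals of one post-exclusion window counts once.

FPKM = count × 10⁹ / (feature length × library size). PROMPT FPKM uses the
post-exclusion *effective* length. Window fold changes are computed on
counts normalized per million mapped fragments — so a sequencing-depth
imbalance between conditions cancels exactly — with a pseudocount `eps`
(default 0.1) added to both means.

## Differential expression

The fold change is `log2((mean tumor FPKM + eps)/(mean normal FPKM + eps))`
with `eps = 0.1` FPKM: extreme published fold changes imply near-zero
denominators, and a small pseudocount keeps those finite without visibly
distorting moderately expressed genes. Gates: `|log2fc| >= 1` *inclusive*
("2-fold increases or decreases" read as reaching 2-fold) and `p < alpha`
*strict* (default `alpha = 0.01`). No multiple-testing correction by
default, mirroring the raw-p rule of the analysis being reproduced.

Three tests on `log2(FPKM + eps)` are provided, and the choice matters at
this design's sample sizes:

* `permutation` (package default): exact label permutation on the
  difference of group means — full enumeration when there are at most 252
  labelings, else seeded Monte-Carlo. It is distribution-free and honest,
  but its granularity is a hard floor: at 3 vs 3 the two-sided p can never
  go below 2/C(6,3) = 0.1, so **no gene can reach p < 0.01 in a 3 vs 3
  subtype comparison under this test**. It is the right null-calibrated
  reference, not a practical caller at n = 3.
* `welch`: the unequal-variance t-test, vectorized. Usable at n = 3 but
  pays for per-gene variance estimation from two degrees of freedom.
* `moderated`: limma's empirical-Bayes moderated t with a mean–variance
  trend. Borrowing variance strength across genes is the standard remedy at
  2–3 samples per group, and this is the default for the packaged pipeline
  (`run_all()`) and the recovery analyses.

Unpaired group comparisons are used (matching the semantics of the original
tool chain) even though the design is paired.

## Multivariate analysis

Rows (genes) are z-scored (mean 0, sample sd 1; constant rows dropped with
a warning). Clustering uses dissimilarity `1 − tau` where `tau` is Kendall's
tau-b (tie-corrected; `stats::cor`): identical rankings give distance 0,
exact reversals 2. Agglomeration is average linkage via `stats::hclust`;
an O(n³) reference implementation in the tests certifies the cophenetic
structure. PCA decomposes the row-z-scored matrix by SVD; variance
fractions are squared singular values over their total, cross-checked in
the tests against an eigen decomposition of the Gram matrix. Spearman
correlations use mid-ranks; the Pearson-on-ranks identity is tested with
and without ties.

## Cross-species correlation

A subtype's signature is the set of genes passing the DEG gates in that
subtype and no other (exclusive Venn cells, direction ignored), summarized
as mean `log2(FPKM + eps)` over the subtype's tumor samples (a fold-change
summary is available — which quantity the original analysis correlated is
not recoverable, so both are provided and neither is claimed as canonical).
Signatures are mapped through a one-to-one ortholog table (duplicates
dropped) and compared to each human-subtype vector by Spearman correlation;
p-values are exact-permutation for n ≤ 8 mapped genes and t-approximate
above. Fewer than 3 mapped genes skips the subtype with a reason.

## Gene–PROMPT pairs

With one fold change per gene and one per window, a per-pair correlation
coefficient is undefined; "correlation" at pair level is implemented as
*sign concordance* under the dual gates (gene: p < 0.01 and |log2fc| ≥ 1;
window: |log2fc| ≥ 1). Pairs whose mean raw window count falls below
`min_mean_count` (default 5 fragments — low-expression windows are where
spurious negative calls concentrate) are flagged, not removed. The overall
Pearson correlation of (gene, window) log2 fold changes is reported across
the positive class (negatives being low-count-suspect), with an
all-classified variant alongside.

## qPCR validation

ΔCt = Ct(target) − Ct(reference); ΔΔCt subtracts the calibrator — by
default the mean normal ΔCt per gene (`calibrator = "paired"` uses each
pair's own normal); relative expression is 2^−ΔΔCt. The Mann–Whitney U is
computed from mid-ranks and reported in min-orientation
(U = min(U₁, U₂)). For tie-free data the two-sided p is exact: the null
distribution of U is enumerated by a subset-sum dynamic program over rank
sums (integer counts in doubles, exact far beyond n = 12 + 12), and
p = 2·P(U ≤ u), capped at 1 — valid because the null is symmetric. Ties
divert to seeded Monte-Carlo permutation. The empirical ROC uses the
tie-corrected rank AUC in direction-agnostic orientation (AUC ≥ 0.5, the
min-U convention, so up- and down-regulated genes report on the same
scale), with the identity AUC = 1 − U/(n₁n₂) holding on tie-free data; the
95% CI uses the Hanley–McNeil variance formula (the original CI method is
unstated, so no printed interval is claimed).

## The synthetic data: what it emulates, and what it does not

The generator (`sim_config()` defaults) encodes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_animals_per_subtype` | 3/3/2 | paired tumor+normal per animal |
| `planted_log2fc_range` | (2, 3) | planted effect magnitudes, half up/half down |
| `nb_dispersion` | 0.05 | NB dispersion; 0 → Poisson |
| `library_size` | 2×10⁵ | expected fragments per sample |
| `n_genes` | 200 | toy genome size |
| `n_planted_degs_overall` | 20 | shared tumor signature |
| `n_planted_degs_per_subtype` | 12 | subtype-specific effects |
| `prompt_fragment_rate` / `prompt_fold` | 20 / 4 | active-window fragment rate and activation ratio |
| `prompt_background_rate` | 8 | fragments per unplanted window |
| `qpcr_n_pairs` / `qpcr_sd_ct` | 12 / 1.5 | qPCR panel size; Ct spread in cycles |

Design choices worth stating:

* **Negative binomial counts** (mean/dispersion): the standard bulk RNA-seq
  noise model; dispersion → 0 reduces to Poisson, which the tests use for
  sharp Monte-Carlo checks of planted means.
* **Paired animal effects**: each animal has a log-normal baseline effect
  (sd `animal_effect_sd` = 0.25 on the log scale) shared by its pair and
  damped in tumors, so normals vary more between animals than tumors — the
  clustering pattern the paired design exhibits. Because the effect is a
  global per-sample multiplier, FPKM normalization cancels it; it shapes
  clustering geometry, not DEG calls.
* **Planted genes are mid-expression** (0.05–0.2% of library mass). In
  real libraries DEGs are a tiny fraction of sequenced mass; at 200 genes
  an unconstrained planting would let planted genes dominate the library
  total and total-count normalization would visibly attenuate up-regulated
  fold changes — a desk-scale artifact, not a property of the method.
* **PROMPT planting avoids shared windows.** Divergent gene pairs closer
  than 1500 bp have superimposed upstream windows; a planted signal there
  would be diluted by the neighbor window's background fragments. Planted
  pairs are drawn from up-regulated overall DEGs with non-empty,
  non-shared windows; shared windows still exist in the genome and still
  exercise the exclusion logic.
* **qPCR noise of 1.5 cycles** reflects biological between-animal spread
  (technical qPCR noise alone is a fraction of a cycle), which puts AUCs
  in the realistic 0.7–0.95 band rather than at 1.0.
* The human panel's matched column is a noisy increasing monotone
  transform of one canine signature profile — rank correlation with the
  source is high *by construction*; the other columns are independent.

What the generator does **not** emulate: read sequences and alignment
ambiguity, isoform structure (one transcript per gene; regions are
per-gene), GC/length biases, exosome sensitivity of PROMPTs, correlated
gene–gene expression modules, and human-panel replicate structure. Passing
recovery tests therefore certify the *pipeline's statistics and
bookkeeping*, not robustness to alignment or annotation error in real data.

## Problem sizes and determinism

The shipped analyses and tests run at the design scale: 200-gene genomes,
16 samples, 20-seed recovery sweeps, exact enumeration up to 6 vs 6 against
the DP null, and 100 random annotations against the per-base oracle —
sizes at which every oracle is exact and the full suite runs in minutes.
Every stochastic step is a pure function of an integer seed: generators
seed locally per stage, Monte-Carlo tests take explicit seeds, and
`run_all()` writes a manifest of MD5 checksums that reruns reproduce
byte-for-byte.

## Known limitations

* The permutation test's granularity makes it unusable for p < 0.01 calls
  at n ≤ 4 per group; this is a property of exact tests, documented rather
  than patched.
* Per-pair gene–PROMPT "correlation" is sign concordance, the strongest
  statement one fold change per side supports.
* The unpaired comparisons leave pairing information unused; a paired mode
  for qPCR calibration exists, and pairing-aware DE would be a natural
  extension.
* FPKM inherits total-count normalization's compositional sensitivity;
  the generator controls it by construction, real data may not.
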