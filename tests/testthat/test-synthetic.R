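test_that("configuration validation catches impossible settings", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = -1), "configuration error")
  expect_error(sim_config(planted_log2fc_range = c(0.5, 2)),
               "magnitudes must be >= 1")
  expect_error(sim_config(gene_length_range = c(3000, 1000)),
               "gene_length_range")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
})

test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 7, n_genes = 50)
  t1 <- withr::local_tempfile(fileext = ".gtf")
  t2 <- withr::local_tempfile(fileext = ".gtf")
  generate_annotation(cfg, gtf_path = t1)
  generate_annotation(cfg, gtf_path = t2)
  expect_identical(readLines(t1), readLines(t2))

  ann <- generate_annotation(cfg)
  e1 <- simulate_expression(ann, cfg)
  e2 <- simulate_expression(ann, cfg)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$truth, e2$truth)
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))

  reg <- build_prompt_regions(ann)
  pl <- planted_prompt_pairs(e1$truth, reg, cfg)
  f1 <- simulate_prompt_fragments(ann, reg, pl, e1$meta, cfg)
  f2 <- simulate_prompt_fragments(ann, reg, pl, e1$meta, cfg)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("empty and near-degenerate annotations are handled", {
  cfg <- sim_config(seed = 1, n_genes = 0)
  ann <- generate_annotation(cfg)
  expect_length(ann$genes, 0)
  tmp <- withr::local_tempfile(fileext = ".gtf")
  generate_annotation(cfg, gtf_path = tmp)
  back <- parse_gtf(tmp)
  expect_length(back$genes, 0)
  expect_error(simulate_expression(ann, cfg), "empty")
})

test_that("gaps drawn below 1500 bp produce windows needing exclusion", {
  cfg <- sim_config(seed = 5, n_genes = 40,
                    intergenic_gap_range = c(500L, 1400L))
  ann <- generate_annotation(cfg)
  gaps <- start(ann$genes)[-1] - end(ann$genes)[-length(ann$genes)]
  gaps <- gaps[gaps > 0]  # within-chromosome neighbors only
  expect_true(any(gaps < 1500))
  reg <- build_prompt_regions(ann)
  expect_true(any(reg$summary$effective_length < 1500))
})

test_that("genes are never nested within a strand and both strands occur", {
  cfg <- sim_config(seed = 9, n_genes = 60)
  ann <- generate_annotation(cfg)
  expect_setequal(unique(as.character(strand(ann$genes))), c("+", "-"))
  for (ch in unique(as.character(seqnames(ann$genes)))) {
    g <- ann$genes[as.character(seqnames(ann$genes)) == ch]
    g <- g[order(start(g))]
    expect_true(all(diff(start(g)) > 0))
    expect_true(all(end(g)[-length(g)] < start(g)[-1]))  # disjoint layout
  }
})

test_that("truth table has the configured number of rows per subtype", {
  cfg <- sim_config(seed = 2, n_genes = 150, n_planted_degs_overall = 8,
                    n_planted_degs_per_subtype = 4)
  ann <- generate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  tab <- table(expr$truth$subtype)
  expect_equal(as.integer(tab[c("complex", "ductal", "simple")]), rep(4L, 3))
  expect_equal(as.integer(tab["overall"]), 8L)
  expect_true(all(abs(expr$truth$log2fc) >= 1))
  expect_false(anyDuplicated(expr$truth$gene_id) > 0)
})

test_that("in the Poisson limit a planted 4-fold effect is recovered in the mean", {
  # dispersion 0, no animal effects: tumor/normal mean ratio of a planted
  # log2fc = 2 gene converges to 4 (Monte-Carlo over >= 1000 draws)
  cfg <- sim_config(seed = 21, n_genes = 100, nb_dispersion = 0,
                    animal_effect_sd = 0,
                    planted_log2fc_range = c(2, 2),
                    n_planted_degs_per_subtype = 0,
                    n_planted_degs_overall = 4)
  ann <- generate_annotation(cfg)
  tot_t <- 0; tot_n <- 0
  for (s in 1:80) {
    cfg_s <- sim_config(seed = 21 + s, n_genes = 100, nb_dispersion = 0,
                        animal_effect_sd = 0,
                        planted_log2fc_range = c(2, 2),
                        n_planted_degs_per_subtype = 0,
                        n_planted_degs_overall = 4)
    expr <- simulate_expression(ann, cfg_s)
    up <- expr$truth$gene_id[expr$truth$log2fc > 0]
    tum <- expr$meta$condition == "tumor"
    tot_t <- tot_t + sum(expr$counts[up, tum])
    tot_n <- tot_n + sum(expr$counts[up, !tum])
  }
  expect_equal(tot_t / tot_n, 4, tolerance = 0.01)
})

test_that("PROMPT fragment rates express the planted activation", {
  cfg <- sim_config(seed = 31, n_genes = 80,
                    prompt_fragment_rate = 20, prompt_fold = 4,
                    prompt_background_rate = 0)
  ann <- generate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  reg <- build_prompt_regions(ann)
  pl <- planted_prompt_pairs(expr$truth, reg, cfg)
  fr <- simulate_prompt_fragments(ann, reg, pl, expr$meta, cfg)
  counts <- count_fragments(reg$intervals, fr, strand_mode = "ignore")
  tum <- expr$meta$sample_id[expr$meta$condition == "tumor"]
  nor <- expr$meta$sample_id[expr$meta$condition == "normal"]
  tum <- intersect(tum, colnames(counts)); nor <- intersect(nor, colnames(counts))
  # background rate 0 -> unplanted windows have zero counts
  bg <- setdiff(rownames(counts), pl$gene_id)
  expect_true(all(counts[bg, ] == 0))
  pos <- pl$gene_id[pl$class == "positive"]
  ratio <- mean(counts[pos, tum, drop = FALSE]) /
    mean(counts[pos, nor, drop = FALSE])
  expect_gt(ratio, 2)
  neg <- pl$gene_id[pl$class == "negative"]
  if (length(neg))
    expect_lt(mean(counts[neg, tum, drop = FALSE]) /
              mean(counts[neg, nor, drop = FALSE]), 1 / 2)
  # fragments never extend past chromosome bounds
  sl <- GenomeInfoDb::seqlengths(fr)[as.character(seqnames(fr))]
  expect_true(all(end(fr) <= sl))
  expect_true(all(start(fr) >= 1))
})

test_that("planted genes with fully excluded windows are reported and skipped", {
  df <- data.frame(chrom = "chr1", start = c(10001, 8001),
                   end = c(12000, 10000), strand = c("+", "-"),
                   gene_id = c("focal", "cover"), stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 50000L))
  reg <- build_prompt_regions(models)
  cfg <- sim_config(seed = 1)
  meta <- sample_metadata(cfg)
  planted <- data.frame(gene_id = "focal", class = "positive",
                        stringsAsFactors = FALSE)
  expect_warning(
    fr <- simulate_prompt_fragments(models, reg, planted, meta, cfg),
    "fully excluded")
  expect_identical(attr(fr, "skipped"), "focal")
})

test_that("qPCR tables have the right shape and exact noise-free arithmetic", {
  cfg0 <- sim_config(seed = 4, qpcr_sd_ct = 0, qpcr_n_pairs = 6)
  q <- simulate_qpcr(cfg0, fold_changes = c(G16 = 16, GHALF = 0.5))
  expect_equal(nrow(q), 2 * 6 * 2)
  expect_equal(as.integer(table(q$gene)), c(12L, 12L))
  rel <- ddct(q)
  # noise-free: every tumor ddCt is exactly -log2(fold)
  expect_equal(rel$ddct[rel$gene == "G16" & rel$condition == "tumor"],
               rep(-4, 6))
  expect_equal(rel$rel_expr[rel$gene == "G16" & rel$condition == "tumor"],
               rep(16, 6))
  expect_equal(rel$ddct[rel$gene == "GHALF" & rel$condition == "tumor"],
               rep(1, 6))
  expect_error(simulate_qpcr(sim_config(seed = 1, qpcr_n_pairs = 1)),
               "qpcr_n_pairs")
})

test_that("a planted fold of 1 gives unit relative expression on average", {
  tot <- 0; n <- 0
  for (s in 1:30) {
    cfg <- sim_config(seed = 400 + s, qpcr_sd_ct = 0.6, qpcr_n_pairs = 12)
    rel <- ddct(simulate_qpcr(cfg, fold_changes = c(FLAT = 1)))
    # log-scale mean is the unbiased summary of a log-normal ratio
    tot <- tot + sum(-rel$ddct); n <- n + nrow(rel)
  }
  expect_equal(2^(tot / n), 1, tolerance = 0.05)
})

test_that("the human panel's planted column is a monotone image of the canine profile", {
  profile <- stats::setNames(seq(2, 8, length.out = 20),
                             sprintf("CFG%05d", 1:20))
  omap <- simulate_ortholog_map(names(profile))
  panel <- simulate_human_panel(profile, omap, matched_subtype = "TNBC",
                                noise_sd = 0, seed = 3)
  expect_equal(dim(panel), c(20L, 4L))
  # zero noise: the transform preserves ranks exactly
  expect_equal(cor(profile, panel[omap$human_gene_id, "TNBC"],
                   method = "spearman"), 1)
})
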