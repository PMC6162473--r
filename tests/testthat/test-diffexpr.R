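# two-group FPKM matrix with explicit metadata
two_group <- function(tumor, normal, genes = paste0("g", seq_len(nrow(tumor)))) {
  m <- cbind(tumor, normal)
  colnames(m) <- c(paste0("T", seq_len(ncol(tumor))),
                   paste0("N", seq_len(ncol(normal))))
  rownames(m) <- genes
  meta <- data.frame(
    sample_id = colnames(m),
    animal_id = colnames(m),
    condition = rep(c("tumor", "normal"), c(ncol(tumor), ncol(normal))),
    subtype = "complex", stringsAsFactors = FALSE)
  list(m = m, meta = meta)
}

test_that("log2 fold change uses the pseudocount exactly as defined", {
  d <- two_group(matrix(8, 1, 3), matrix(2, 1, 3))
  rec <- test_differential(d$m, d$meta, "overall", test = "welch")
  expect_equal(rec$log2fc, log2(8.1 / 2.1), tolerance = 1e-12)
  expect_equal(round(rec$log2fc, 3), 1.948)
  expect_true(abs(rec$log2fc) >= 1)  # clears the 2-fold gate
})

test_that("identical groups give zero fold change, p = 1, direction none", {
  x <- matrix(rep(c(3, 7, 1), 6), 3, 6, byrow = FALSE)
  d <- two_group(x[, 1:3], x[, 4:6])
  rec <- test_differential(d$m, d$meta, "overall", test = "permutation")
  expect_equal(rec$log2fc, rep(0, 3))
  expect_equal(rec$p_value, rep(1, 3))
  expect_equal(rec$direction, rep("none", 3))
  expect_false(any(rec$passes))
})

test_that("threshold semantics: 2-fold inclusive, alpha strict", {
  # exact 2-fold after pseudocount: (2.1 + 0.1) / (1 + 0.1) = 2
  d <- two_group(matrix(2.1, 1, 4), matrix(1, 1, 4))
  rec <- test_differential(d$m, d$meta, "overall", test = "welch")
  expect_equal(rec$log2fc, 1)
  expect_true(rec$passes)  # |log2fc| exactly 1 passes
  expect_equal(rec$direction, "up")

  # exact permutation at 3v3: perfectly separated groups give p = 2/20 = 0.1;
  # at alpha = 0.1 the strict inequality rejects the call
  d2 <- two_group(matrix(c(10, 11, 12), 1, 3), matrix(c(1, 2, 3), 1, 3))
  rec2 <- test_differential(d2$m, d2$meta, "overall", test = "permutation",
                            alpha = 0.1)
  expect_equal(rec2$p_value, 0.1)
  expect_false(rec2$passes)
  rec3 <- test_differential(d2$m, d2$meta, "overall", test = "permutation",
                            alpha = 0.11)
  expect_true(rec3$passes)
})

test_that("a lone planted gene is the only one called on clean data", {
  cfg <- sim_config(seed = 17, n_genes = 10, nb_dispersion = 0,
                    animal_effect_sd = 0,
                    n_planted_degs_overall = 1,
                    n_planted_degs_per_subtype = 0,
                    planted_log2fc_range = c(3, 3))
  ann <- generate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  rec <- test_differential(expr, comparison = "overall", test = "welch")
  expect_equal(sum(rec$passes), 1L)
  expect_equal(rec$gene_id[rec$passes], expr$truth$gene_id)
})

test_that("group-size preconditions produce a named error", {
  d <- two_group(matrix(1, 2, 1), matrix(1, 2, 3))
  expect_error(test_differential(d$m, d$meta, "overall"), "overall")
  d2 <- two_group(matrix(1, 2, 3), matrix(1, 2, 3))
  expect_error(test_differential(d2$m, d2$meta, "ductal"), "ductal")
})

test_that("permutation p-values are valid under the global null", {
  # 3v3 exact enumeration: granularity 1/20; over many null genes the
  # rejection rate at level alpha stays below alpha + granularity (+ MC slack)
  set.seed(42)
  y <- matrix(2^rnorm(300 * 6, 5, 1), 300, 6)
  d <- two_group(y[, 1:3], y[, 4:6])
  rec <- test_differential(d$m, d$meta, "overall", test = "permutation")
  for (alpha in c(0.1, 0.2, 0.5)) {
    rate <- mean(rec$p_value <= alpha)
    expect_lt(rate, alpha + 1 / 20 + 3 * sqrt(alpha / 300))
  }
  expect_true(all(rec$p_value >= 1 / 10))  # two-sided floor at 3v3
})

test_that("Monte-Carlo permutation branch engages beyond 252 labelings and is seeded", {
  set.seed(5)
  y <- 2^matrix(rnorm(20 * 16, 5, 0.5), 20, 16)
  d <- two_group(y[, 1:8], y[, 9:16])
  r1 <- test_differential(d$m, d$meta, "overall", test = "permutation",
                          n_perm = 300, seed = 3)
  r2 <- test_differential(d$m, d$meta, "overall", test = "permutation",
                          n_perm = 300, seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(all(r1$p_value >= 1 / 301))
})

test_that("Venn partition performs exact set algebra", {
  mk <- function(up, down) {
    data.frame(gene_id = c(up, down),
               comparison = "x",
               log2fc = c(rep(2, length(up)), rep(-2, length(down))),
               p_value = 0.001,
               direction = c(rep("up", length(up)), rep("down", length(down))),
               passes = TRUE, stringsAsFactors = FALSE)
  }
  part <- partition_subtypes(list(
    complex = mk(c("a", "b"), "z1"),
    ductal = mk(c("b", "c"), "z1"),
    simple = mk(c("b", "d"), "z2")))
  cells <- part$up$cells
  expect_equal(cells[["complex&ductal&simple"]], "b")
  expect_equal(cells[["complex"]], "a")
  expect_equal(cells[["ductal"]], "c")
  expect_equal(cells[["simple"]], "d")
  expect_equal(sort(unlist(part$up$sets, use.names = FALSE)),
               c("a", "b", "b", "b", "c", "d"))
  expect_equal(part$down$cells[["complex&ductal"]], "z1")
  expect_equal(part$down$cells[["simple"]], "z2")
  # three-way is inside every pairwise intersection
  for (pair in c("complex&ductal", "complex&simple", "ductal&simple"))
    expect_true(all(cells[["complex&ductal&simple"]] %in%
                    union(cells[[pair]], cells[["complex&ductal&simple"]])))
  # disjoint sets: every shared cell empty
  part2 <- partition_subtypes(list(
    complex = mk("a", character()), ductal = mk("b", character()),
    simple = mk("c", character())))
  expect_equal(lengths(part2$up$cells)[4:7], c(`complex&ductal` = 0L,
               `complex&simple` = 0L, `ductal&simple` = 0L,
               `complex&ductal&simple` = 0L))
})

test_that("per-subtype up + down counts equal total passing records", {
  cfg <- sim_config(seed = 23)
  ann <- generate_annotation(cfg)
  expr <- simulate_expression(ann, cfg)
  recs <- lapply(c("complex", "ductal", "simple"), function(s)
    test_differential(expr, comparison = s, test = "moderated"))
  names(recs) <- c("complex", "ductal", "simple")
  part <- partition_subtypes(recs)
  for (s in names(recs)) {
    expect_equal(length(part$up$sets[[s]]) + length(part$down$sets[[s]]),
                 sum(recs[[s]]$passes))
    expect_equal(length(part$passing[[s]]), sum(recs[[s]]$passes))
  }
})

test_that("DEG summary ranks by signed fold change with documented tie-break", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3"), comparison = "overall",
    log2fc = c(2, -3, 1), p_value = c(0.001, 0.0005, 0.002),
    direction = c("up", "down", "up"), passes = TRUE,
    stringsAsFactors = FALSE)
  top <- summarize_degs(rec, n = 1)
  expect_equal(top$gene_id[top$direction == "up"], "g1")
  expect_equal(top$gene_id[top$direction == "down"], "g2")
  expect_equal(top$neg_log10_p[top$gene_id == "g2"], -log10(0.0005))
  expect_equal(round(-log10(0.00005), 6), 4.30103)

  tie <- data.frame(
    gene_id = c("zzz", "aaa", "mmm"), comparison = "overall",
    log2fc = c(2, 2, 2), p_value = 0.001, direction = "up", passes = TRUE,
    stringsAsFactors = FALSE)
  expect_equal(summarize_degs(tie, n = 2)$gene_id, c("aaa", "mmm"))
})
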