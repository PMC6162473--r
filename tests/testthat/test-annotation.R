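test_that("GTF coordinates map to gene models with strand-aware TSS", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    "#!sequence-region chr1 1 10000",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"gplus\";",
    "chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tgene_id \"gplus\"; transcript_id \"gplus.t1\";",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tgene_id \"gminus\";",
    "chr1\tsrc\texon\t5001\t6000\t.\t-\t.\tgene_id \"gminus\"; transcript_id \"gminus.t1\";"),
    tmp)
  models <- parse_gtf(tmp)
  g <- models$genes
  expect_equal(g$gene_id, c("gminus", "gplus"))
  tss <- tss_positions(models)
  # 1-based closed spans: + strand TSS at the span start, - at the span end
  expect_equal(unname(tss["gplus"]), 1001L)
  expect_equal(unname(tss["gminus"]), 6000L)
  expect_equal(unname(GenomeInfoDb::seqlengths(g)["chr1"]), 10000L)
})

test_that("write_gtf/parse_gtf round-trips gene models losslessly", {
  cfg <- sim_config(seed = 3, n_genes = 30)
  models <- generate_annotation(cfg)
  tmp <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(models, tmp)
  back <- parse_gtf(tmp)
  expect_equal(back$genes$gene_id, models$genes$gene_id)
  expect_equal(start(back$genes), start(models$genes))
  expect_equal(end(back$genes), end(models$genes))
  expect_equal(as.character(strand(back$genes)),
               as.character(strand(models$genes)))
  expect_equal(GenomeInfoDb::seqlengths(back$genes),
               GenomeInfoDb::seqlengths(models$genes))
  # second serialization is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("unknown strand in a GTF is rejected", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\tgene\t100\t200\t.\t*\t.\tgene_id \"g1\";", tmp)
  expect_error(parse_gtf(tmp), "strand")
  expect_error(parse_gtf("/nonexistent/file.gtf"), "not found")
})

test_that("nominal PROMPT windows sit upstream of the TSS on each strand", {
  df <- data.frame(chrom = "chr1", start = c(5001, 20001),
                   end = c(8000, 28000), strand = c("+", "-"),
                   gene_id = c("gp", "gm"), stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 50000L))
  reg <- build_prompt_regions(models, window = 1500)
  gp <- reg$intervals[reg$intervals$gene_id == "gp"]
  expect_equal(c(start(gp), end(gp)), c(3501, 5000))
  gm <- reg$intervals[reg$intervals$gene_id == "gm"]
  expect_equal(c(start(gm), end(gm)), c(28001, 29500))
  expect_equal(reg$summary$effective_length, c(1500L, 1500L))
})

test_that("a neighbor transcript punches a hole in the window", {
  # + strand gene with TSS at 5001; neighbor spans [4001, 4600]
  df <- data.frame(chrom = "chr1", start = c(5001, 4001),
                   end = c(8000, 4600), strand = c("+", "+"),
                   gene_id = c("focal", "nb"), stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 50000L))
  reg <- build_prompt_regions(models, window = 1500)
  iv <- reg$intervals[reg$intervals$gene_id == "focal"]
  expect_equal(start(iv), c(3501, 4601))
  expect_equal(end(iv), c(4000, 5000))
  expect_equal(reg$summary$effective_length[reg$summary$gene_id == "focal"],
               900L)
  # matches the per-base membership oracle exactly
  expect_identical(region_positions(reg, "focal"),
                   oracle_prompt_positions(models, "focal"))
})

test_that("windows are clipped at chromosome bounds and can be fully excluded", {
  df <- data.frame(chrom = "chr1", start = c(501, 9501, 2001),
                   end = c(1500, 9900, 9400), strand = c("+", "-", "+"),
                   gene_id = c("edge_left", "edge_right", "blanket"),
                   stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 10000L))
  reg <- build_prompt_regions(models, window = 1500)
  s <- reg$summary
  expect_equal(s$effective_length[s$gene_id == "edge_left"], 500L)
  expect_equal(s$effective_length[s$gene_id == "edge_right"], 100L)
  expect_error(build_prompt_regions(models, window = 0), "window")
})

test_that("fully consumed windows are retained and flagged empty", {
  # focal + gene at 10001; another gene covers its whole upstream window
  df <- data.frame(chrom = "chr1", start = c(10001, 8001),
                   end = c(12000, 10000), strand = c("+", "-"),
                   gene_id = c("focal", "cover"), stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 50000L))
  reg <- build_prompt_regions(models)
  s <- reg$summary
  expect_true(s$empty[s$gene_id == "focal"])
  expect_equal(s$effective_length[s$gene_id == "focal"], 0L)
  expect_equal(nrow(s), 2L)  # still present in the summary
  # same-strand policy ignores the opposite-strand cover gene
  reg2 <- build_prompt_regions(models, exclusion = "same-strand")
  expect_false(reg2$summary$empty[reg2$summary$gene_id == "focal"])
})

test_that("interval subtraction equals the per-base oracle on random annotations", {
  for (s in 1:25) {
    cfg <- sim_config(seed = 7000 + s, n_genes = 20, n_chromosomes = 1,
                      intergenic_gap_range = c(100L, 2500L))
    models <- generate_annotation(cfg)
    reg <- build_prompt_regions(models)
    for (gid in models$genes$gene_id) {
      expect_identical(region_positions(reg, gid),
                       oracle_prompt_positions(models, gid))
    }
  }
})

test_that("no PROMPT interval overlaps another gene's span", {
  cfg <- sim_config(seed = 11, n_genes = 50)
  models <- generate_annotation(cfg)
  reg <- build_prompt_regions(models)
  hits <- findOverlaps(reg$intervals, models$genes, ignore.strand = TRUE)
  cross <- reg$intervals$gene_id[queryHits(hits)] !=
    models$genes$gene_id[subjectHits(hits)]
  expect_equal(sum(cross), 0L)
})

test_that("mirroring coordinates and strands mirrors the PROMPT regions", {
  cfg <- sim_config(seed = 13, n_genes = 25, n_chromosomes = 1)
  models <- generate_annotation(cfg)
  L <- unname(GenomeInfoDb::seqlengths(models$genes)["chr1"])
  g <- models$genes
  mirror_df <- data.frame(chrom = "chr1",
                          start = L + 1L - end(g), end = L + 1L - start(g),
                          strand = ifelse(as.character(strand(g)) == "+", "-", "+"),
                          gene_id = g$gene_id, stringsAsFactors = FALSE)
  mirrored <- toy_models(mirror_df, seqlens = c(chr1 = L))
  r1 <- build_prompt_regions(models)
  r2 <- build_prompt_regions(mirrored)
  for (gid in g$gene_id) {
    p1 <- region_positions(r1, gid)
    p2 <- region_positions(r2, gid)
    expect_identical(sort(L + 1L - p2), p1)
  }
})

test_that("BED round trip preserves intervals and 0-based convention on disk", {
  df <- data.frame(chrom = "chr1", start = 3501, end = 5000, strand = "+",
                   gene_id = "g1", stringsAsFactors = FALSE)
  models <- toy_models(df, seqlens = c(chr1 = 10000L))
  reg <- build_prompt_regions(models)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, tmp)
  line <- strsplit(readLines(tmp)[1], "\t")[[1]]
  expect_equal(as.integer(line[2]), 2000L)  # 1-based 2001 -> BED start 2000
  expect_equal(as.integer(line[3]), 3500L)
  back <- read_regions_bed(tmp)
  expect_equal(start(back), 2001L)
  expect_equal(end(back), 3500L)
  expect_equal(back$gene_id, "g1")
  # modified-GTF output is 1-based inclusive
  tmpg <- withr::local_tempfile(fileext = ".gtf")
  write_regions_gtf(reg, tmpg)
  gl <- strsplit(readLines(tmpg)[1], "\t")[[1]]
  expect_equal(as.integer(gl[4]), 2001L)
  expect_equal(as.integer(gl[5]), 3500L)
})
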