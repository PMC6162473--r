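#' TSV I/O helpers
#'
#' Thin wrappers fixing the dialect used by every stage output: tab
#' separated, header, no quoting, no row names (matrices keep rownames in a
#' leading `feature_id` column).
#'
#' @param x data.frame or matrix.
#' @param path File path.
#' @return `path` (write) / data.frame or matrix (read).
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run configuration for the end-to-end pipeline
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; also seeds the simulation config unless one is
#'   supplied.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param fc,alpha,prompt_fc,window,min_mean_count,eps The analysis
#'   thresholds: DEG fold gate, DEG p gate, PROMPT fold gate, PROMPT window
#'   size (bp), low-count flag threshold (fragments), FPKM pseudocount.
#' @param deg_test Test used for DEG calling in the standard run (default
#'   `"moderated"`; see [test_differential()] for why the permutation test
#'   cannot reach p < 0.01 at 2-3 animals per subtype).
#' @param stages Named logical toggles:
#'   annotation, regions, expression, prompt, deg, multivariate,
#'   cross_species, prompt_corr, validation.
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, sim = sim_config(seed = seed),
                       fc = 2, alpha = 0.01, prompt_fc = 2, window = 1500,
                       min_mean_count = 5, eps = 0.1, deg_test = "moderated",
                       stages = NULL) {
  all_stages <- c("annotation", "regions", "expression", "prompt", "deg",
                  "multivariate", "cross_species", "prompt_corr", "validation")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) st[names(stages)] <- stages
  if (any(c(fc, alpha, prompt_fc, window, min_mean_count) <= 0) || window <= 0)
    stop("thresholds and window must be positive")
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 fc = fc, alpha = alpha, prompt_fc = prompt_fc,
                 window = window, min_mean_count = min_mean_count, eps = eps,
                 deg_test = deg_test, stages = st),
            class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes every enabled stage in dependency order: annotation ->
#' PROMPT regions -> expression -> PROMPT fragments/counts -> DEG calling
#' (overall + per subtype) and Venn partitioning -> clustering/PCA/Spearman
#' multiscatter -> cross-species panel correlation -> gene-PROMPT pair
#' classification -> qPCR validation statistics. Every output is a TSV (or
#' GTF/BED/Newick/JSON) under `config$outdir`, and a manifest listing each
#' file with row count and MD5 checksum is written last; a rerun with the
#' same configuration reproduces the manifest checksums exactly.
#'
#' A stage whose prerequisite is toggled off raises a dependency error
#' naming both stages; a failing stage aborts the run with a `FAILED`
#' marker file naming it.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest data.frame (`file`, `rows`, `md5`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  need <- function(stage, dep) {
    if (!st[[dep]])
      stop("stage '", stage, "' requires stage '", dep, "' to be enabled")
  }
  paths <- character()
  logf <- file.path(config$outdir, "run.log")
  cat("", file = logf)
  note <- function(...) cat(paste0(..., "\n"), file = logf, append = TRUE)
  emit <- function(name, writer) {
    p <- file.path(config$outdir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }
  fail_marker <- file.path(config$outdir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  run <- function() {
    models <- regions <- expr <- frag <- pcounts <- degs <- part <- NULL
    if (st[["annotation"]]) {
      models <- generate_annotation(config$sim)
      emit("annotation.gtf", function(p) write_gtf(models, p))
      note("annotation: ", length(models$genes), " genes")
      # parse what was written: downstream consumes the serialized form
      models <- parse_gtf(file.path(config$outdir, "annotation.gtf"))
    }
    if (st[["regions"]]) {
      need("regions", "annotation")
      regions <- build_prompt_regions(models, window = config$window)
      emit("prompt_regions.bed", function(p) write_regions_bed(regions, p))
      emit("prompt_regions.gtf", function(p) write_regions_gtf(regions, p))
      emit("prompt_regions_summary.tsv",
           function(p) write_tsv(regions$summary, p))
      note("regions: ", sum(!regions$summary$empty), " non-empty windows")
    }
    if (st[["expression"]]) {
      need("expression", "annotation")
      expr <- simulate_expression(models, config$sim)
      emit("counts.tsv", function(p) write_tsv(expr$counts, p))
      emit("fpkm.tsv", function(p) write_tsv(expr$fpkm, p))
      emit("sample_meta.tsv", function(p) write_tsv(expr$meta, p))
      emit("truth_degs.tsv", function(p) write_tsv(expr$truth, p))
      note("expression: ", nrow(expr$counts), " genes x ", ncol(expr$counts),
           " samples")
    }
    if (st[["prompt"]]) {
      need("prompt", "regions"); need("prompt", "expression")
      planted <- planted_prompt_pairs(expr$truth, regions, config$sim)
      frag <- simulate_prompt_fragments(models, regions, planted, expr$meta,
                                        config$sim)
      emit("prompt_fragments.bed", function(p) write_fragments_bed(frag, p))
      emit("planted_prompt_pairs.tsv", function(p) write_tsv(planted, p))
      pcounts <- count_fragments(regions$intervals, frag,
                                 strand_mode = "ignore")
      emit("prompt_counts.tsv", function(p) write_tsv(pcounts, p))
      note("prompt: ", length(frag), " fragments over ",
           nrow(pcounts), " windows")
    }
    if (st[["deg"]]) {
      need("deg", "expression")
      cmps <- c("overall", names(config$sim$n_animals_per_subtype))
      degs <- lapply(cmps, function(cmp)
        test_differential(expr, comparison = cmp, test = config$deg_test,
                          fc = config$fc, alpha = config$alpha,
                          eps = config$eps, seed = config$seed))
      names(degs) <- cmps
      for (cmp in cmps)
        emit(paste0("deg_", cmp, ".tsv"), function(p) write_tsv(degs[[cmp]], p))
      part <- partition_subtypes(degs[setdiff(cmps, "overall")])
      venn <- do.call(rbind, lapply(c("up", "down"), function(dir)
        data.frame(direction = dir, cell = names(part[[dir]]$cells),
                   n = lengths(part[[dir]]$cells),
                   genes = vapply(part[[dir]]$cells, paste,
                                  character(1), collapse = ","),
                   stringsAsFactors = FALSE)))
      emit("venn_cells.tsv", function(p) write_tsv(venn, p))
      emit("top_degs.tsv", function(p) write_tsv(summarize_degs(degs$overall), p))
      note("deg: ", sum(degs$overall$passes), " overall DEGs; per-subtype ",
           paste(vapply(setdiff(cmps, "overall"),
                        function(s) sum(degs[[s]]$passes), numeric(1)),
                 collapse = "/"))
    }
    if (st[["multivariate"]]) {
      need("multivariate", "deg")
      deg_genes <- degs$overall$gene_id[degs$overall$passes]
      if (length(deg_genes) >= 3) {
        sub <- expr$fpkm[deg_genes, , drop = FALSE]
        z <- suppressWarnings(zscore_rows(sub))
        tree <- hcluster(z, axis = "samples")
        emit("cluster_samples.nwk", function(p) export_newick(tree, p))
        pc <- pca_samples(sub)
        emit("pca_scores.tsv", function(p)
          write_tsv(data.frame(sample_id = rownames(pc$scores),
                               pc$scores[, seq_len(min(3, ncol(pc$scores))),
                                         drop = FALSE]), p))
        emit("pca_variance.tsv", function(p)
          write_tsv(data.frame(component = seq_along(pc$variance_explained),
                               variance_explained = pc$variance_explained), p))
      } else note("multivariate: skipped (fewer than 3 overall DEGs)")
      subs <- names(config$sim$n_animals_per_subtype)
      prof_genes <- sort(unique(unlist(lapply(subs, function(s)
        degs[[s]]$gene_id[degs[[s]]$passes]))))
      if (length(prof_genes) >= 3) {
        prof <- vapply(subs, function(s) {
          tum <- expr$meta$sample_id[expr$meta$subtype == s &
                                     expr$meta$condition == "tumor"]
          rowMeans(log2(expr$fpkm[prof_genes, tum, drop = FALSE] + config$eps))
        }, numeric(length(prof_genes)))
        sp <- spearman_pairs(prof)
        emit("subtype_spearman.tsv", function(p) write_tsv(sp$r, p))
      }
      note("multivariate: done")
    }
    if (st[["cross_species"]]) {
      need("cross_species", "deg")
      sigs <- suppressWarnings(build_signatures(part, expr, eps = config$eps))
      nonempty <- names(sigs)[vapply(sigs, function(s) length(s$genes) > 0,
                                     logical(1))]
      if (length(nonempty)) {
        omap <- simulate_ortholog_map(rownames(expr$fpkm))
        matched <- nonempty[1]
        panel <- simulate_human_panel(sigs[[matched]]$profile, omap,
                                      matched_subtype = "HER2",
                                      seed = config$seed)
        xs <- do.call(rbind, lapply(nonempty, function(s) {
          res <- suppressWarnings(correlate_with_panel(sigs[[s]], omap, panel))
          if (nrow(res)) cbind(canine_subtype = s, res) else NULL
        }))
        emit("ortholog_map.tsv", function(p) write_tsv(omap, p))
        emit("human_panel.tsv", function(p) write_tsv(panel, p))
        if (!is.null(xs))
          emit("cross_species.tsv", function(p) write_tsv(xs, p))
        note("cross_species: matched panel planted for ", matched)
      } else note("cross_species: skipped (all signatures empty)")
    }
    if (st[["prompt_corr"]]) {
      need("prompt_corr", "prompt"); need("prompt_corr", "deg")
      pfc <- prompt_fold_changes(pcounts, expr$meta, eps = config$eps)
      pairs <- classify_pairs(degs$overall, pfc,
                              min_mean_count = config$min_mean_count,
                              fc = config$prompt_fc, alpha = config$alpha)
      emit("prompt_pairs.tsv", function(p) write_tsv(pairs$pairs, p))
      emit("prompt_summary.json", function(p)
        jsonlite::write_json(pairs$summary, p, auto_unbox = TRUE,
                             digits = NA, na = "null"))
      note("prompt_corr: ", pairs$summary$n_positive, " positive / ",
           pairs$summary$n_negative, " negative pairs")
    }
    if (st[["validation"]]) {
      qpcr <- simulate_qpcr(config$sim)
      emit("qpcr_ct.tsv", function(p) write_tsv(qpcr, p))
      val <- validate_qpcr(qpcr)
      emit("qpcr_validation.tsv", function(p) write_tsv(val, p))
      note("validation: ", nrow(val), " genes tested")
    }
  }
  ok <- tryCatch({ run(); TRUE }, error = function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })

  manifest <- data.frame(
    file = basename(paths),
    rows = unname(vapply(paths, function(p) length(readLines(p, warn = FALSE)),
                         integer(1))),
    md5 = unname(tools::md5sum(paths)),
    row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Choose planted gene-PROMPT pairs from the expression truth table
#'
#' Positive pairs (PROMPT signal up with the gene) and negative pairs
#' (PROMPT signal down while the gene is up) are drawn deterministically
#' from the up-regulated overall-planted DEGs whose PROMPT window survived
#' exclusion and does not share bases with another gene's window, positives
#' first in truth-table order. Overall DEGs are used because the
#' gene-PROMPT classification runs against the overall tumor/normal
#' comparison.
#'
#' @param truth Truth table from [simulate_expression()].
#' @param regions A `prompt_regions` object.
#' @param config A [sim_config()].
#' @return data.frame `gene_id`, `class`.
#' @export
planted_prompt_pairs <- function(truth, regions, config) {
  up <- truth$gene_id[truth$log2fc > 0 & truth$subtype == "overall"]
  ok <- regions$summary$gene_id[!regions$summary$empty]
  # avoid windows sharing bases with another gene's window (divergent gene
  # pairs): background fragments of the superimposed window would dilute
  # the planted signal
  iv <- regions$intervals
  h <- GenomicRanges::findOverlaps(iv, iv, ignore.strand = TRUE)
  cross <- iv$gene_id[S4Vectors::queryHits(h)] !=
    iv$gene_id[S4Vectors::subjectHits(h)]
  shared <- unique(iv$gene_id[S4Vectors::queryHits(h)[cross]])
  up <- up[up %in% setdiff(ok, shared)]
  npos <- min(config$n_prompt_positive, length(up))
  pos <- up[seq_len(npos)]
  rest <- setdiff(up, pos)
  nneg <- min(config$n_prompt_negative, length(rest))
  neg <- rest[seq_len(nneg)]
  data.frame(gene_id = c(pos, neg),
             class = rep(c("positive", "negative"), c(npos, nneg)),
             stringsAsFactors = FALSE)
}
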