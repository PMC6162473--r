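#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: eight animals in three histological
#' subtypes (3 complex, 3 ductal, 2 simple), each contributing a paired
#' tumor/normal sample; subtype-specific differential expression planted at
#' 2-fold or more; negative-binomial count noise; PROMPT signal planted
#' upstream of a subset of up-regulated genes; and a 12-pair qPCR validation
#' panel.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration, so identical configurations give byte-identical outputs.
#' @param n_chromosomes,n_genes Genome size of the toy annotation.
#' @param gene_length_range,intergenic_gap_range bp ranges genes/gaps are
#'   drawn from (uniform). A gap lower bound below 1500 guarantees some
#'   PROMPT windows overlap an upstream neighbour, exercising the exclusion.
#' @param n_animals_per_subtype Named integer vector
#'   (`complex`, `ductal`, `simple`); each animal yields one tumor and one
#'   matched normal sample.
#' @param n_planted_degs_overall Number of genes shifted in every tumor
#'   sample regardless of subtype (the shared tumor signature; these are the
#'   genes PROMPT signal is planted next to).
#' @param n_planted_degs_per_subtype Number of genes given a subtype-specific
#'   tumor shift.
#' @param planted_log2fc_range Magnitude range for planted effects; both
#'   bounds must be at least 1 so every planted gene clears the 2-fold gate
#'   by construction. Signs are assigned half up / half down.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 means Poisson.
#' @param library_size Expected fragments per sample.
#' @param animal_effect_sd sd (log scale) of the per-animal log-normal
#'   baseline effect shared by a tumor/normal pair; damped in tumors.
#' @param n_prompt_positive,n_prompt_negative Planted gene-PROMPT pairs:
#'   positives have elevated window signal in tumors, negatives depleted.
#' @param prompt_fragment_rate Expected fragments in the active condition of
#'   a planted window.
#' @param prompt_fold Activation ratio between the two conditions of a
#'   planted window (>= 2).
#' @param prompt_background_rate Expected fragments in every unplanted
#'   window (and the inactive side floor).
#' @param qpcr_n_pairs Tumor/normal pairs in the qPCR panel.
#' @param qpcr_sd_ct Gaussian noise sd on Ct values, in cycles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       n_genes = 200L,
                       gene_length_range = c(1000L, 3000L),
                       intergenic_gap_range = c(300L, 3000L),
                       n_animals_per_subtype = c(complex = 3L, ductal = 3L,
                                                 simple = 2L),
                       n_planted_degs_overall = 20L,
                       n_planted_degs_per_subtype = 12L,
                       planted_log2fc_range = c(2, 3),
                       nb_dispersion = 0.05,
                       library_size = 2e5,
                       animal_effect_sd = 0.25,
                       n_prompt_positive = 4L,
                       n_prompt_negative = 2L,
                       prompt_fragment_rate = 20,
                       prompt_fold = 4,
                       prompt_background_rate = 8,
                       qpcr_n_pairs = 12L,
                       qpcr_sd_ct = 1.5) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              n_animals_per_subtype = n_animals_per_subtype,
              n_planted_degs_overall = as.integer(n_planted_degs_overall),
              n_planted_degs_per_subtype = as.integer(n_planted_degs_per_subtype),
              planted_log2fc_range = planted_log2fc_range,
              nb_dispersion = nb_dispersion, library_size = library_size,
              animal_effect_sd = animal_effect_sd,
              n_prompt_positive = as.integer(n_prompt_positive),
              n_prompt_negative = as.integer(n_prompt_negative),
              prompt_fragment_rate = prompt_fragment_rate,
              prompt_fold = prompt_fold,
              prompt_background_rate = prompt_background_rate,
              qpcr_n_pairs = as.integer(qpcr_n_pairs),
              qpcr_sd_ct = qpcr_sd_ct)
  counts <- c(cfg$n_chromosomes, cfg$n_genes, cfg$n_planted_degs_overall,
              cfg$n_planted_degs_per_subtype,
              cfg$n_prompt_positive, cfg$n_prompt_negative, cfg$qpcr_n_pairs,
              cfg$n_animals_per_subtype)
  if (any(counts < 0)) stop("configuration error: counts must be >= 0")
  if (cfg$n_chromosomes < 1) stop("configuration error: need >= 1 chromosome")
  if (any(diff(cfg$gene_length_range) < 0) || cfg$gene_length_range[1] < 1)
    stop("configuration error: invalid gene_length_range")
  if (any(diff(cfg$intergenic_gap_range) < 0) || cfg$intergenic_gap_range[1] < 0)
    stop("configuration error: invalid intergenic_gap_range")
  if (any(abs(cfg$planted_log2fc_range) < 1))
    stop("configuration error: planted log2 fold-change magnitudes must be >= 1")
  if (cfg$nb_dispersion < 0) stop("configuration error: nb_dispersion < 0")
  if (cfg$library_size <= 0) stop("configuration error: library_size <= 0")
  if (cfg$prompt_fold < 2)
    stop("configuration error: prompt_fold must be >= 2")
  if (cfg$qpcr_sd_ct < 0) stop("configuration error: qpcr_sd_ct < 0")
  if (!all(c("complex", "ductal", "simple") %in% names(cfg$n_animals_per_subtype)))
    stop("configuration error: n_animals_per_subtype needs complex/ductal/simple")
  structure(cfg, class = "sim_config")
}

# Seed the RNG reproducibly for one generator stage.
.stage_seed <- function(cfg, offset) {
  set.seed((cfg$seed + offset) %% .Machine$integer.max)
}

#' Generate a toy genome annotation
#'
#' Genes are laid out sequentially along each chromosome with uniform random
#' lengths and intergenic gaps, random strand, and 1-3 exons, so genes are
#' never nested within a strand. Chromosome lengths are set to the last gene
#' end plus a margin.
#'
#' @param config A [sim_config()].
#' @param gtf_path Optional path; when given the annotation is also written
#'   as GTF (see [write_gtf()]).
#' @return A [gene_models] object.
#' @export
generate_annotation <- function(config, gtf_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .stage_seed(config, 11L)
  n <- config$n_genes
  per_chrom <- if (n > 0) {
    tabulate(rep_len(seq_len(config$n_chromosomes), n),
             nbins = config$n_chromosomes)
  } else rep(0L, config$n_chromosomes)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))

  if (n == 0L) {
    genes <- GenomicRanges::GRanges(gene_id = character())
    GenomeInfoDb::seqlevels(genes) <- chrom_names
    GenomeInfoDb::seqlengths(genes) <- rep(10000L, config$n_chromosomes)
    models <- gene_models(genes, GenomicRanges::GRangesList())
    if (!is.null(gtf_path)) write_gtf(models, gtf_path)
    return(models)
  }

  chrom <- rep(chrom_names, per_chrom)
  gaps <- sample(config$intergenic_gap_range[1]:config$intergenic_gap_range[2],
                 n, replace = TRUE)
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- end <- integer(n)
  seqlens <- integer(length(chrom_names))
  names(seqlens) <- chrom_names
  idx <- split(seq_len(n), factor(chrom, levels = chrom_names))
  for (ci in chrom_names) {
    ii <- idx[[ci]]
    if (!length(ii)) { seqlens[ci] <- 10000L; next }
    # sequential layout: gene k starts one gap after gene k-1 ends
    st <- 1L + cumsum(gaps[ii]) + c(0L, cumsum(lens[ii])[-length(ii)])
    start[ii] <- st
    end[ii] <- st + lens[ii] - 1L
    seqlens[ci] <- end[ii[length(ii)]] + 2000L
  }
  gene_id <- sprintf("CFG%05d", seq_len(n))
  genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                  strand = strand, gene_id = gene_id)
  GenomeInfoDb::seqlevels(genes) <- chrom_names
  GenomeInfoDb::seqlengths(genes) <- seqlens

  exon_iv <- lapply(seq_len(n), function(i) .draw_exons(start[i], end[i]))
  nex <- lengths(exon_iv)
  flat <- unlist(IRanges::IRangesList(exon_iv))
  ex_gr <- GenomicRanges::GRanges(rep(chrom, nex), flat,
                                  strand = rep(strand, nex))
  exl <- GenomicRanges::split(ex_gr, factor(rep(gene_id, nex), levels = gene_id))
  GenomeInfoDb::seqlevels(exl) <- chrom_names
  GenomeInfoDb::seqlengths(exl) <- seqlens
  models <- gene_models(genes, exl)
  if (!is.null(gtf_path)) write_gtf(models, gtf_path)
  models
}

# 1-3 exons spanning [start, end]: first starts at start, last ends at end.
.draw_exons <- function(start, end) {
  len <- end - start + 1L
  k <- sample(1:3, 1L)
  if (k == 1L || len < 6L * k)
    return(IRanges::IRanges(start, end))
  cuts <- sort(sample(seq.int(start + 1L, end - 1L), 2L * (k - 1L)))
  starts <- c(start, cuts[seq(2, length(cuts), by = 2)] + 1L)
  ends <- c(cuts[seq(1, length(cuts), by = 2)], end)
  keep <- ends >= starts
  IRanges::IRanges(starts[keep], ends[keep])
}

#' Sample metadata for the paired design
#'
#' @param config A [sim_config()].
#' @return data.frame with `sample_id`, `animal_id`, `condition`
#'   (tumor/normal) and `subtype`; two rows per animal.
#' @export
sample_metadata <- function(config) {
  subs <- rep(names(config$n_animals_per_subtype),
              config$n_animals_per_subtype)
  animal <- sprintf("A%02d", seq_along(subs))
  data.frame(
    sample_id = c(paste0(animal, "_T"), paste0(animal, "_N")),
    animal_id = rep(animal, 2),
    condition = rep(c("tumor", "normal"), each = length(animal)),
    subtype = rep(subs, 2),
    stringsAsFactors = FALSE)
}

#' Simulate paired tumor/normal expression
#'
#' Per-gene baseline abundances are log-normal; each animal carries a
#' log-normal baseline effect shared by its tumor/normal pair, with the
#' effect damped in tumors so that tumors cluster more tightly than normals
#' (the pattern the paired design is built to show).
#' `n_planted_degs_overall` genes are shifted in every tumor sample (the
#' shared tumor signature); in addition, for each subtype,
#' `n_planted_degs_per_subtype` genes get a signed log2 fold change (drawn
#' from `planted_log2fc_range`, half up / half down) applied only in tumor
#' samples of that subtype. Counts are negative-binomial around these means
#' (Poisson when `nb_dispersion` is 0) and converted to FPKM with exonic
#' feature lengths and per-sample total counts.
#'
#' @param models A [gene_models] annotation.
#' @param config A [sim_config()].
#' @return List of class `expression_set`: `counts`, `fpkm` (genes x
#'   samples), `lengths` (exonic bp per gene), `meta` (sample metadata) and
#'   `truth` (data.frame `gene_id`, `subtype`, `log2fc` of planted effects).
#' @export
simulate_expression <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(models$genes) == 0) stop("annotation is empty")
  .stage_seed(config, 23L)
  meta <- sample_metadata(config)
  gids <- models$genes$gene_id
  ng <- length(gids)
  lens <- vapply(gids, function(g) {
    e <- models$exons[[g]]
    if (is.null(e) || length(e) == 0) {
      i <- match(g, gids)
      BiocGenerics::width(models$genes)[i]
    } else sum(BiocGenerics::width(e))
  }, numeric(1))

  base <- exp(stats::rnorm(ng, log(30), 1))
  base <- base / sum(base) * config$library_size
  names(base) <- gids

  # Planted effects go into mid-expression genes (0.05-0.2% of library
  # mass) so that, as in real libraries where DEGs are a tiny mass
  # fraction, the planted fold changes survive total-count normalization
  # instead of being eaten by compositional shift of the library total.
  share <- base / sum(base)
  eligible <- gids[share >= 5e-4 & share <= 2e-3]
  n_needed <- config$n_planted_degs_overall +
    config$n_planted_degs_per_subtype * length(config$n_animals_per_subtype)
  if (length(eligible) < n_needed) {
    extra <- gids[order(abs(log(share) - log(1e-3)))]
    eligible <- utils::head(unique(c(eligible, extra)), max(n_needed, 1))
  }

  subtypes <- names(config$n_animals_per_subtype)
  truth <- list()
  avail <- eligible
  k0 <- min(config$n_planted_degs_overall, length(avail))
  if (k0 > 0) {
    picked <- sample(avail, k0)
    avail <- setdiff(avail, picked)
    mag <- stats::runif(k0, config$planted_log2fc_range[1],
                        config$planted_log2fc_range[2])
    truth[["overall"]] <- data.frame(
      gene_id = picked, subtype = "overall",
      log2fc = rep(c(1, -1), length.out = k0) * mag,
      stringsAsFactors = FALSE)
  }
  for (st in subtypes) {
    k <- min(config$n_planted_degs_per_subtype, length(avail))
    if (k == 0) next
    picked <- sample(avail, k)
    avail <- setdiff(avail, picked)
    mag <- stats::runif(k, config$planted_log2fc_range[1],
                        config$planted_log2fc_range[2])
    sign <- rep(c(1, -1), length.out = k)
    truth[[st]] <- data.frame(gene_id = picked, subtype = st,
                              log2fc = sign * mag, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), subtype = character(),
               log2fc = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  animals <- unique(meta$animal_id)
  a_eff <- stats::setNames(
    exp(stats::rnorm(length(animals), 0, config$animal_effect_sd)), animals)

  counts <- matrix(0, nrow = ng, ncol = nrow(meta),
                   dimnames = list(gids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    tumor <- meta$condition[j] == "tumor"
    # tumors share the damped animal effect -> tighter grouping than normals
    eff <- if (tumor) a_eff[meta$animal_id[j]]^0.3 else a_eff[meta$animal_id[j]]
    mu <- base * eff
    if (tumor && nrow(truth)) {
      pl <- truth[truth$subtype %in% c(meta$subtype[j], "overall"), ]
      mu[pl$gene_id] <- mu[pl$gene_id] * 2^pl$log2fc
    }
    counts[, j] <- if (config$nb_dispersion == 0) {
      stats::rpois(ng, mu)
    } else {
      stats::rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
    }
  }
  libsizes <- colSums(counts)
  fpkm_m <- fpkm_matrix(counts, lens, libsizes)
  structure(list(counts = counts, fpkm = fpkm_m, lengths = lens,
                 meta = meta, truth = truth),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", nrow(x$truth), "planted effects\n")
  invisible(x)
}

#' Simulate stranded PROMPT-window fragments
#'
#' Every non-empty PROMPT window receives Poisson background fragments in
#' every sample. Windows of positively planted genes get
#' `prompt_fragment_rate` expected fragments in tumor samples and
#' `prompt_fragment_rate / prompt_fold` in normals; negatively planted
#' windows the reverse. Fragments are ~100 bp intervals placed uniformly in
#' the window's retained intervals, random strand, clipped at chromosome
#' bounds. Planted genes whose window was fully excluded are reported with a
#' warning and skipped.
#'
#' @param models A [gene_models] annotation (for chromosome bounds).
#' @param regions A `prompt_regions` object from [build_prompt_regions()].
#' @param planted data.frame with `gene_id` and `class`
#'   (`"positive"`/`"negative"`); may have zero rows.
#' @param meta Sample metadata ([sample_metadata()]).
#' @param config A [sim_config()].
#' @return `GRanges` of fragments with `sample_id`, sorted; attribute
#'   `skipped` lists planted genes with empty windows.
#' @export
simulate_prompt_fragments <- function(models, regions, planted, meta, config) {
  stopifnot(inherits(config, "sim_config"))
  .stage_seed(config, 37L)
  smry <- regions$summary
  skipped <- character()
  if (nrow(planted)) {
    bad <- planted$gene_id[planted$gene_id %in% smry$gene_id[smry$empty] |
                           !planted$gene_id %in% smry$gene_id]
    if (length(bad)) {
      warning("planted PROMPT gene(s) with fully excluded window skipped: ",
              paste(bad, collapse = ", "))
      skipped <- bad
      planted <- planted[!planted$gene_id %in% bad, , drop = FALSE]
    }
  }
  ivs <- regions$intervals
  seqlens <- GenomeInfoDb::seqlengths(ivs)
  gids <- smry$gene_id[!smry$empty]
  if (length(gids) == 0) {
    out <- GenomicRanges::GRanges(sample_id = character())
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(regions$intervals)
    GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(regions$intervals)
    attr(out, "skipped") <- skipped
    return(out)
  }
  active <- stats::setNames(rep("background", length(gids)), gids)
  if (nrow(planted)) active[planted$gene_id] <- planted$class
  is_tumor <- meta$condition == "tumor"
  hi <- config$prompt_fragment_rate
  lo <- config$prompt_fragment_rate / config$prompt_fold
  bg <- config$prompt_background_rate

  # rate matrix windows x samples, then one Poisson draw per cell
  rate <- matrix(bg, nrow = length(gids), ncol = nrow(meta),
                 dimnames = list(gids, meta$sample_id))
  rate[active == "positive", is_tumor] <- hi
  rate[active == "positive", !is_tumor] <- lo
  rate[active == "negative", is_tumor] <- lo
  rate[active == "negative", !is_tumor] <- hi
  nfr <- matrix(stats::rpois(length(rate), rate), nrow = nrow(rate),
                dimnames = dimnames(rate))

  iv_by_gene <- split(seq_along(ivs), ivs$gene_id)
  iv_w <- BiocGenerics::width(ivs)
  frag_gene <- rep(rep(gids, ncol(nfr)), as.vector(nfr))
  frag_sample <- rep(rep(meta$sample_id, each = nrow(nfr)), as.vector(nfr))
  ntot <- length(frag_gene)
  if (ntot) {
    # pick an interval per fragment, width-weighted within its window
    pick <- integer(ntot)
    for (gid in unique(frag_gene)) {
      sel <- frag_gene == gid
      cand <- iv_by_gene[[gid]]
      pick[sel] <- if (length(cand) == 1) cand else
        sample(cand, sum(sel), replace = TRUE, prob = iv_w[cand])
    }
    st <- BiocGenerics::start(ivs)[pick] +
      floor(stats::runif(ntot) * pmax(iv_w[pick] - 1L, 1L))
    flen <- pmax(20L, as.integer(round(stats::rnorm(ntot, 100, 10))))
    en <- st + flen - 1L
    chrom <- as.character(GenomeInfoDb::seqnames(ivs))[pick]
    lim <- seqlens[chrom]
    en <- ifelse(is.na(lim), en, pmin(en, lim))
    st <- pmax(st, 1L)
    out <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(st, en),
      strand = sample(c("+", "-"), ntot, replace = TRUE),
      sample_id = frag_sample)
    out <- suppressWarnings(BiocGenerics::sort(out))
  } else {
    out <- GenomicRanges::GRanges(sample_id = character())
  }
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(ivs)
  GenomeInfoDb::seqlengths(out) <- seqlens
  attr(out, "skipped") <- skipped
  out
}

#' Write / read fragment records as BED6
#'
#' Name column carries the sample id; 0-based half-open on disk.
#'
#' @param fragments `GRanges` with `sample_id`.
#' @param path BED path.
#' @return `path` (write) or a `GRanges` (read).
#' @export
write_fragments_bed <- function(fragments, path) {
  gr <- fragments
  gr$name <- gr$sample_id
  gr$score <- 0L
  gr$sample_id <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
                         strand = BiocGenerics::strand(gr),
                         sample_id = gr$name)
}

#' Simulate a qPCR Ct table
#'
#' For each target gene and tumor/normal pair, the reference-gene Ct is
#' constant in expectation (20 cycles) and the target Ct sits at a per-gene
#' baseline offset, shifted by `-log2(fold)` in tumor samples, with Gaussian
#' noise of sd `qpcr_sd_ct` on every measured Ct. With zero noise the
#' delta-delta-Ct of every pair is exactly `-log2(fold)`.
#'
#' @param config A [sim_config()]; needs `qpcr_n_pairs >= 2`.
#' @param fold_changes Named numeric of true tumor/normal expression ratios
#'   per target gene (values < 1 are down-regulated).
#' @return data.frame with `sample_id`, `pair_id`, `condition`, `gene`,
#'   `ct_target`, `ct_reference`; `2 * qpcr_n_pairs` rows per gene.
#' @export
simulate_qpcr <- function(config,
                          fold_changes = c(FN1 = 4, BGN = 3, SCD = 0.25)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$qpcr_n_pairs < 2) stop("qpcr_n_pairs must be >= 2")
  .stage_seed(config, 53L)
  np <- config$qpcr_n_pairs
  sdct <- config$qpcr_sd_ct
  rows <- list(); ri <- 0L
  for (g in names(fold_changes)) {
    dct_base <- stats::runif(1, 3, 8)
    for (p in seq_len(np)) {
      pair <- sprintf("P%02d", p)
      for (cond in c("tumor", "normal")) {
        shift <- if (cond == "tumor") -log2(fold_changes[[g]]) else 0
        ct_ref <- 20 + stats::rnorm(1, 0, sdct)
        ct_tar <- ct_ref + dct_base + shift + stats::rnorm(1, 0, sdct)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          sample_id = paste0(pair, "_", toupper(substr(cond, 1, 1))),
          pair_id = pair, condition = cond, gene = g,
          ct_target = ct_tar, ct_reference = ct_ref,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a one-to-one ortholog map
#'
#' @param gene_ids Canine gene ids.
#' @return data.frame `canine_gene_id`, `human_gene_id` (one-to-one).
#' @export
simulate_ortholog_map <- function(gene_ids) {
  data.frame(canine_gene_id = gene_ids,
             human_gene_id = sub("^CFG", "HSG", gene_ids),
             stringsAsFactors = FALSE)
}

#' Simulate a human-subtype expression panel
#'
#' Builds a panel of per-subtype human expression vectors over the orthologs
#' of the supplied canine profile. The `matched_subtype` column is a noisy
#' increasing monotone transform of the canine profile (so its rank
#' correlation with the source is high by construction); the remaining
#' columns are independent draws.
#'
#' @param canine_profile Named numeric (canine gene ids -> log-scale
#'   expression summary).
#' @param ortholog_map From [simulate_ortholog_map()].
#' @param matched_subtype Which human subtype column carries the planted
#'   match (default `"HER2"`).
#' @param subtypes Human subtype labels.
#' @param noise_sd Gaussian noise added to the matched column.
#' @param seed RNG seed.
#' @return Matrix human genes x human subtypes.
#' @export
simulate_human_panel <- function(canine_profile, ortholog_map,
                                 matched_subtype = "HER2",
                                 subtypes = c("HER2", "ER", "ER_HER2", "TNBC"),
                                 noise_sd = 0.3, seed = 1L) {
  stopifnot(matched_subtype %in% subtypes)
  set.seed(seed)
  hids <- ortholog_map$human_gene_id[match(names(canine_profile),
                                           ortholog_map$canine_gene_id)]
  keep <- !is.na(hids)
  x <- canine_profile[keep]
  panel <- matrix(stats::rnorm(sum(keep) * length(subtypes), 5, 2),
                  nrow = sum(keep), ncol = length(subtypes),
                  dimnames = list(hids[keep], subtypes))
  # monotone transform: affine + mild curvature preserves ranks exactly
  panel[, matched_subtype] <- 0.8 * x + 0.05 * (x - mean(x))^2 * sign(x - mean(x)) +
    stats::rnorm(sum(keep), 0, noise_sd)
  panel
}
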