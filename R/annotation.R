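#' Gene model container
#'
#' Bundles gene spans, exon structure and chromosome lengths into a single
#' object used by every downstream stage. Coordinates follow the Bioconductor
#' convention (1-based, closed intervals) throughout the package; GTF output
#' is 1-based inclusive and BED output 0-based half-open, as those formats
#' require.
#'
#' @param genes `GRanges` with one range per gene and a `gene_id` metadata
#'   column; strand must be `+` or `-`.
#' @param exons `GRangesList` named by `gene_id`; each element's ranges must
#'   lie within the gene span. Exons are merged (reduced) on construction.
#' @return An object of class `gene_models` with elements `genes` and `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRangesList"))
  if (is.null(genes$gene_id)) stop("genes must carry a 'gene_id' column")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene set")
  if (any(!as.character(BiocGenerics::strand(genes)) %in% c("+", "-")))
    stop("unknown strand character; genes must be stranded '+' or '-'")
  if (!all(names(exons) %in% genes$gene_id))
    stop("exons present for unknown gene_id")
  exons <- GenomicRanges::reduce(exons)
  # exons must sit inside their gene span (vectorized over the unlisted set)
  if (length(exons)) {
    flat <- unlist(exons, use.names = FALSE)
    gid_of <- rep(names(exons), lengths(exons))
    i <- match(gid_of, genes$gene_id)
    bad <- BiocGenerics::start(flat) < BiocGenerics::start(genes)[i] |
           BiocGenerics::end(flat) > BiocGenerics::end(genes)[i]
    if (any(bad))
      stop("exons of ", paste(unique(gid_of[bad]), collapse = ", "),
           " extend beyond the gene span")
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes on",
      length(GenomeInfoDb::seqlevels(x$genes)), "chromosome(s)\n")
  invisible(x)
}

#' Transcription start sites
#'
#' The TSS is the 5' end of the gene span on its own strand: the span start
#' on `+`, the span end on `-`.
#'
#' @param models A `gene_models` object.
#' @return Named integer vector of TSS positions (1-based).
#' @export
tss_positions <- function(models) {
  g <- models$genes
  s <- as.character(BiocGenerics::strand(g))
  tss <- ifelse(s == "+", BiocGenerics::start(g), BiocGenerics::end(g))
  stats::setNames(as.integer(tss), g$gene_id)
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (via \pkg{rtracklayer}) into a
#' [gene_models] object. Lines of type `gene` define spans; `exon` lines are
#' grouped by `gene_id`. Chromosome lengths are recovered from
#' `#!sequence-region` header directives when present (as written by
#' [write_gtf()]); without them, windows can only be clipped at position 1.
#'
#' @param path GTF file path.
#' @return A `gene_models` object.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  body <- grep("^#", readLines(path, warn = FALSE), invert = TRUE,
               value = TRUE)
  gr <- if (length(body)) rtracklayer::import(path, format = "gtf") else
    GenomicRanges::GRanges(type = character())
  if (length(gr) && any(!as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
    stop("unknown strand character in GTF: only '+' and '-' are supported")
  seqlens <- .parse_seqlen_header(path)
  if (length(gr) == 0) {
    genes <- GenomicRanges::GRanges(gene_id = character())
    if (length(seqlens)) {
      GenomeInfoDb::seqlevels(genes) <- names(seqlens)
      GenomeInfoDb::seqlengths(genes) <- seqlens
    }
    return(gene_models(genes, GenomicRanges::GRangesList()))
  }
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (length(genes) == 0 && length(gr) > 0)
    stop("GTF contains no 'gene' features")
  genes <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes), IRanges::ranges(genes),
    strand = BiocGenerics::strand(genes), gene_id = genes$gene_id)
  genes <- genes[order(genes$gene_id)]
  if (length(exons)) {
    ex <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(exons), IRanges::ranges(exons),
      strand = BiocGenerics::strand(exons))
    exl <- GenomicRanges::split(ex, factor(exons$gene_id, levels = genes$gene_id))
  } else {
    exl <- GenomicRanges::split(genes[0], factor(character(), levels = genes$gene_id))
  }
  if (length(seqlens)) {
    lv <- union(GenomeInfoDb::seqlevels(genes), names(seqlens))
    GenomeInfoDb::seqlevels(genes) <- lv
    GenomeInfoDb::seqlengths(genes)[names(seqlens)] <- seqlens
  }
  gene_models(genes, exl)
}

.parse_seqlen_header <- function(path) {
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  hdr <- grep("^#!sequence-region", hdr, value = TRUE)
  if (!length(hdr)) return(integer())
  parts <- strsplit(hdr, "[ \t]+")
  stats::setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
                  vapply(parts, function(p) p[2], character(1)))
}

#' Write gene models as Ensembl-dialect GTF
#'
#' Emits one `gene` line per gene and one `exon` line per exon, 1-based
#' inclusive, with `gene_id`/`transcript_id` attributes, preceded by
#' `#!sequence-region` directives carrying chromosome lengths so that
#' [parse_gtf()] round-trips losslessly.
#'
#' @param models A `gene_models` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  seqlens <- GenomeInfoDb::seqlengths(g)
  hdr <- character()
  if (length(seqlens) && !all(is.na(seqlens)))
    hdr <- sprintf("#!sequence-region %s 1 %d",
                   names(seqlens)[!is.na(seqlens)], seqlens[!is.na(seqlens)])
  lines <- hdr
  if (length(g)) {
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    gene_lines <- sprintf("%s\tmgcprompt\tgene\t%d\t%d\t.\t%s\t.\t%s",
                          as.character(GenomeInfoDb::seqnames(g)),
                          BiocGenerics::start(g), BiocGenerics::end(g),
                          as.character(BiocGenerics::strand(g)), attr_g)
    ex <- models$exons
    exon_lines <- character()
    for (gid in names(ex)) {
      e <- ex[[gid]]
      if (!length(e)) next
      exon_lines <- c(exon_lines, sprintf(
        '%s\tmgcprompt\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
        as.character(GenomeInfoDb::seqnames(e)),
        BiocGenerics::start(e), BiocGenerics::end(e),
        as.character(BiocGenerics::strand(e)), gid, gid))
    }
    # stable order: by chromosome then start, genes before their exons
    lines <- c(hdr, gene_lines, exon_lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build promoter-upstream (PROMPT) regions
#'
#' For each gene the nominal PROMPT window is the `window` bp immediately
#' upstream of the TSS in the gene's own transcriptional orientation
#' (upstream means lower coordinates on `+`, higher on `-`), clipped at the
#' chromosome boundaries. Positions overlapping a transcript of any *other*
#' gene are then subtracted, because signal there cannot be attributed to
#' promoter-upstream transcription of the focal gene. Genes whose window is
#' fully consumed by the exclusion are retained with `effective_length` 0 and
#' flagged.
#'
#' @param models A `gene_models` object.
#' @param window Window size in bp upstream of the TSS (default 1500).
#' @param exclusion What counts as "another gene's transcript" for the
#'   subtraction: `"both-strands"` (default) removes overlap with any other
#'   gene's span regardless of strand, `"same-strand"` only with spans on the
#'   window's own strand, `"exons-only"` only with other genes' exonic bases.
#' @return A `prompt_regions` object: `intervals` (`GRanges`, one row per
#'   retained interval, carrying `gene_id`) and `summary` (data.frame with
#'   `gene_id`, `chrom`, `strand`, `window_length`, `effective_length`,
#'   `empty`).
#' @export
build_prompt_regions <- function(models, window = 1500,
                                 exclusion = c("both-strands", "same-strand",
                                               "exons-only")) {
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  exclusion <- match.arg(exclusion)
  g <- models$genes
  n <- length(g)
  win <- suppressWarnings(
    GenomicRanges::promoters(g, upstream = as.integer(window),
                             downstream = 0L))
  # clip at chromosome bounds (position 1 and seqlength when known)
  newstart <- pmax(BiocGenerics::start(win), 1L)
  seqlens <- GenomeInfoDb::seqlengths(win)[as.character(GenomeInfoDb::seqnames(win))]
  newend <- BiocGenerics::end(win)
  has_len <- !is.na(seqlens)
  newend[has_len] <- pmin(newend[has_len], seqlens[has_len])
  win <- suppressWarnings({
    BiocGenerics::start(win) <- newstart
    BiocGenerics::end(win) <- pmax(newend, newstart - 1L)  # allow empty
    win
  })

  excl <- switch(exclusion,
    "both-strands" = ,
    "same-strand" = GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(g), IRanges::ranges(g),
      strand = BiocGenerics::strand(g), gene_id = g$gene_id),
    "exons-only" = {
      ex <- unlist(models$exons)
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex), IRanges::ranges(ex),
                             strand = BiocGenerics::strand(ex),
                             gene_id = rep(names(models$exons),
                                           lengths(models$exons)))
    })
  ignore_strand <- exclusion != "same-strand"
  hits <- GenomicRanges::findOverlaps(win, excl, ignore.strand = ignore_strand)
  hits <- hits[g$gene_id[S4Vectors::queryHits(hits)] !=
               excl$gene_id[S4Vectors::subjectHits(hits)]]

  # windows without exclusion hits keep their nominal (clipped) interval;
  # only hit windows need interval subtraction
  out <- lapply(seq_len(n), function(i) {
    w <- IRanges::IRanges(BiocGenerics::start(win)[i], BiocGenerics::end(win)[i])
    if (IRanges::width(w) == 0) IRanges::IRanges() else w
  })
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  excl_r <- IRanges::ranges(excl)
  for (i in unique(qh)) {
    if (length(out[[i]]) == 0) next
    out[[i]] <- IRanges::setdiff(out[[i]], excl_r[sh[qh == i]])
  }
  eff <- vapply(out, function(x) sum(IRanges::width(x)), integer(1))
  nint <- lengths(out)
  intervals <- GenomicRanges::GRanges(
    rep(GenomeInfoDb::seqnames(g), nint),
    unlist(IRanges::IRangesList(out)),
    strand = rep(BiocGenerics::strand(g), nint),
    gene_id = rep(g$gene_id, nint))
  GenomeInfoDb::seqinfo(intervals) <- GenomeInfoDb::seqinfo(g)
  summary <- data.frame(
    gene_id = g$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    strand = as.character(BiocGenerics::strand(g)),
    window_length = as.integer(window),
    effective_length = eff,
    empty = eff == 0L,
    stringsAsFactors = FALSE)
  structure(list(intervals = intervals, summary = summary,
                 window = as.integer(window), exclusion = exclusion),
            class = "prompt_regions")
}

#' @export
print.prompt_regions <- function(x, ...) {
  cat("prompt_regions:", nrow(x$summary), "genes,",
      length(x$intervals), "intervals after", x$exclusion, "exclusion;",
      sum(x$summary$empty), "fully excluded\n")
  invisible(x)
}

#' Write PROMPT regions as BED6
#'
#' One row per retained interval, 0-based half-open, name = `gene_id`,
#' score 0, strand = parent gene strand.
#'
#' @param regions A `prompt_regions` object.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions$intervals
  gr$name <- gr$gene_id
  gr$score <- 0L
  gr$gene_id <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read PROMPT-region intervals back from BED6
#'
#' @param path BED file as written by [write_regions_bed()].
#' @return `GRanges` with a `gene_id` column (from the BED name field).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = BiocGenerics::strand(gr),
                                gene_id = gr$name)
  out
}

#' Write PROMPT regions as a modified GTF
#'
#' Each retained interval becomes an `exon` line (1-based inclusive) whose
#' `gene_id` is the parent gene's id suffixed with `_PROMPT`, i.e. a
#' quantifiable annotation of the promoter-upstream windows.
#'
#' @param regions A `prompt_regions` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_regions_gtf <- function(regions, path) {
  gr <- regions$intervals
  lines <- sprintf(
    '%s\tmgcprompt\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s_PROMPT"; transcript_id "%s_PROMPT.t1";',
    as.character(GenomeInfoDb::seqnames(gr)),
    BiocGenerics::start(gr), BiocGenerics::end(gr),
    as.character(BiocGenerics::strand(gr)), gr$gene_id, gr$gene_id)
  writeLines(lines, path)
  invisible(path)
}
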