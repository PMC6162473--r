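# Fixture builders and independent brute-force oracles shared across tests.
# Oracles deliberately avoid the code paths they check.

# Bioconductor generics resolved explicitly: test code evaluates with the
# package namespace (not the search path) as its enclosure.
GRanges <- GenomicRanges::GRanges
findOverlaps <- GenomicRanges::findOverlaps
start <- BiocGenerics::start
end <- BiocGenerics::end
width <- BiocGenerics::width
strand <- BiocGenerics::strand
seqnames <- GenomeInfoDb::seqnames
queryHits <- S4Vectors::queryHits
subjectHits <- S4Vectors::subjectHits

# Hand-built gene models: df with chrom, start, end, strand, gene_id
toy_models <- function(df, seqlens = NULL, exons = NULL) {
  genes <- GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                   strand = df$strand, gene_id = df$gene_id)
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlevels(genes) <- names(seqlens)
    GenomeInfoDb::seqlengths(genes) <- seqlens
  }
  if (is.null(exons)) {
    exl <- GenomicRanges::split(genes, factor(df$gene_id, levels = df$gene_id))
  } else {
    exl <- exons
  }
  gene_models(genes, exl)
}

# Per-base membership oracle for one gene's PROMPT window: enumerate every
# genomic position of the nominal upstream window, drop positions outside
# the chromosome or inside any other gene's span (policy both-strands).
oracle_prompt_positions <- function(models, gid, window = 1500) {
  g <- models$genes
  i <- match(gid, g$gene_id)
  strand <- as.character(strand(g))[i]
  chrom <- as.character(seqnames(g))[i]
  tss <- if (strand == "+") start(g)[i] else end(g)[i]
  pos <- if (strand == "+") (tss - window):(tss - 1) else (tss + 1):(tss + window)
  pos <- pos[pos >= 1]
  sl <- GenomeInfoDb::seqlengths(g)[chrom]
  if (!is.na(sl)) pos <- pos[pos <= sl]
  others <- g[-i]
  others <- others[as.character(seqnames(others)) == chrom]
  if (length(others)) {
    covered <- unlist(lapply(seq_along(others),
                             function(j) start(others)[j]:end(others)[j]))
    pos <- setdiff(pos, covered)
  }
  sort(pos)
}

# Positions actually covered by a prompt_regions object for one gene.
region_positions <- function(regions, gid) {
  iv <- regions$intervals[regions$intervals$gene_id == gid]
  if (!length(iv)) return(integer())
  sort(unlist(lapply(seq_along(iv), function(j) start(iv)[j]:end(iv)[j])))
}

# Double-loop fragment counting oracle: feature intervals (possibly several
# per feature id) x fragments, >= min_overlap bp, strand rule applied
# per pair; a fragment counts once per feature id.
oracle_count <- function(features, fragments, strand_mode = "ignore",
                         min_overlap = 1) {
  fids <- unique(features$gene_id)
  samples <- unique(fragments$sample_id)
  m <- matrix(0L, length(fids), length(samples),
              dimnames = list(fids, samples))
  for (fi in seq_along(fids)) {
    rows <- which(features$gene_id == fids[fi])
    for (qi in seq_along(fragments)) {
      hit <- FALSE
      for (ri in rows) {
        if (as.character(seqnames(features))[ri] !=
            as.character(seqnames(fragments))[qi]) next
        ov <- min(end(features)[ri], end(fragments)[qi]) -
          max(start(features)[ri], start(fragments)[qi]) + 1
        if (ov < min_overlap) next
        fs <- as.character(strand(features))[ri]
        qs <- as.character(strand(fragments))[qi]
        oks <- switch(strand_mode,
                      ignore = TRUE,
                      same = fs == qs,
                      opposite = fs != qs)
        if (oks) { hit <- TRUE; break }
      }
      if (hit) {
        sj <- match(fragments$sample_id[qi], samples)
        m[fi, sj] <- m[fi, sj] + 1L
      }
    }
  }
  m
}

# O(n^3) average-linkage reference: returns the cophenetic distance matrix.
oracle_average_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- mean(d[clusters[[a]], clusters[[b]]])
      if (h < best[1] - 1e-12) best <- c(h, a, b)
    }
    a <- best[2]; b <- best[3]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- coph[j, i] <- best[1]
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  coph
}

# Brute-force Mann-Whitney null distribution of U by enumerating every
# assignment of n1 ranks out of n1+n2.
oracle_mw_null <- function(n1, n2) {
  N <- n1 + n2
  combs <- utils::combn(N, n1)
  u <- colSums(matrix(seq_len(N)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  tab <- tabulate(u + 1, nbins = n1 * n2 + 1)
  tab / ncol(combs)
}

# Small deterministic fragment set builder
make_fragments <- function(chrom, starts, ends, strands, sample_id = "S1") {
  GRanges(chrom, IRanges::IRanges(starts, ends), strand = strands,
          sample_id = sample_id)
}
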