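#' Count fragments over features
#'
#' A fragment increments a feature's count when it overlaps the feature by
#' at least `min_overlap` bp and satisfies the strand mode. A fragment
#' overlapping k features is counted in all k (multi-assignment); a fragment
#' overlapping several intervals of the same multi-interval feature is
#' counted once for that feature. Fragments on chromosomes absent from the
#' feature set are skipped with a warning and tallied in the `skipped`
#' attribute.
#'
#' @param features `GRanges` with a `gene_id` (or `feature_id`) metadata
#'   column; multiple rows may share an id (multi-interval features such as
#'   PROMPT regions after exclusion).
#' @param fragments `GRanges` with a `sample_id` metadata column.
#' @param strand_mode `"ignore"` (default for unstranded window counting),
#'   `"same"` (fragment strand must equal feature strand; default choice for
#'   gene counting of a stranded library) or `"opposite"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Integer matrix features x samples (rownames = feature ids,
#'   colnames = sample ids present in `fragments`), with attribute
#'   `skipped` = number of fragments on unknown chromosomes.
#' @export
count_fragments <- function(features, fragments,
                            strand_mode = c("ignore", "same", "opposite"),
                            min_overlap = 1L) {
  strand_mode <- match.arg(strand_mode)
  ids <- features$gene_id
  if (is.null(ids)) ids <- features$feature_id
  if (is.null(ids)) stop("features must carry 'gene_id' or 'feature_id'")
  fids <- unique(ids)
  samples <- unique(fragments$sample_id)
  m <- matrix(0L, nrow = length(fids), ncol = length(samples),
              dimnames = list(fids, samples))

  known <- as.character(GenomeInfoDb::seqnames(fragments)) %in%
    unique(as.character(GenomeInfoDb::seqnames(features)))
  nskip <- sum(!known)
  if (nskip > 0) {
    warning(nskip, " fragment(s) on chromosomes absent from features skipped")
    fragments <- fragments[known]
  }
  if (length(fragments) == 0 || length(features) == 0) {
    attr(m, "skipped") <- nskip
    return(m)
  }
  frg <- fragments
  if (strand_mode == "opposite") {
    s <- as.character(BiocGenerics::strand(frg))
    BiocGenerics::strand(frg) <- ifelse(s == "+", "-", ifelse(s == "-", "+", s))
  }
  # harmonize seqlevels so findOverlaps does not error on disjoint sets
  lv <- union(GenomeInfoDb::seqlevels(features), GenomeInfoDb::seqlevels(frg))
  GenomeInfoDb::seqlevels(features) <- lv
  GenomeInfoDb::seqlevels(frg) <- lv
  hits <- GenomicRanges::findOverlaps(
    features, frg, minoverlap = as.integer(min_overlap),
    ignore.strand = (strand_mode == "ignore"))
  if (length(hits)) {
    key <- data.frame(
      fid = ids[S4Vectors::queryHits(hits)],
      frag = S4Vectors::subjectHits(hits), stringsAsFactors = FALSE)
    key <- unique(key)  # one count per fragment-feature pair
    key$sample <- frg$sample_id[key$frag]
    tab <- table(factor(key$fid, levels = fids),
                 factor(key$sample, levels = samples))
    m[] <- as.integer(tab)
  }
  attr(m, "skipped") <- nskip
  m
}

#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = count x 10^9 / (feature_length x library_size): the count scaled
#' to a 1 kb feature and a library of one million mapped fragments.
#'
#' @param count Fragment count(s), non-negative.
#' @param feature_length Feature length(s) in bp, > 0.
#' @param library_size Total mapped fragments in the sample, > 0.
#' @return FPKM value(s); 0 count gives 0.
#' @export
fpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e9 / (feature_length * library_size)
}

#' FPKM matrix from a count matrix
#'
#' @param counts Features x samples count matrix.
#' @param feature_lengths bp per feature (recycled down rows).
#' @param library_sizes Mapped fragments per sample; default the column sums
#'   of `counts`.
#' @return Matrix of FPKM values with the same dimnames.
#' @export
fpkm_matrix <- function(counts, feature_lengths,
                        library_sizes = colSums(counts)) {
  if (any(feature_lengths <= 0)) stop("feature_length must be > 0")
  if (any(library_sizes <= 0)) stop("library_size must be > 0")
  sweep(counts / feature_lengths, 2, library_sizes, "/") * 1e9
}
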