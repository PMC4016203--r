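#' Per-base coverage profile of one exon
#'
#' Positional counts along an exon in one library: entry `p` is the
#' number of alignment records with an aligned block covering exon base
#' `p`. CIGAR `N`/`D` gaps contribute no coverage, and read bases
#' outside the exon contribute nothing. Profiles are accumulated through
#' block-interval difference arrays, O(blocks) per record.
#'
#' @param exon A single-row `exon_table` (or list with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates).
#' @param aln An `mc_alignments` table.
#' @return Integer vector of length `end - start`.
#' @examples
#' aln <- data.frame(qname = "r1", flag = 0L, rname = "chr1", pos = 106L,
#'                   cigar = "10M", nm = 0L, nh = 1L)
#' coverage_profile(list(chrom = "chr1", start = 100, end = 110), aln)
#' @export
coverage_profile <- function(exon, aln) {
  refs <- attr(aln, "references")
  if (!is.null(refs) && !(exon$chrom %in% names(refs)))
    stop("exon reference '", exon$chrom,
         "' is not a reference sequence of the alignment set")
  L <- as.integer(exon$end - exon$start)
  d <- integer(L + 1L)
  if (nrow(aln)) {
    bl <- ref_blocks(aln)
    on_ref <- as.character(GenomicRanges::seqnames(bl)) == exon$chrom
    s1 <- exon$start + 1L             # 1-based inclusive exon start
    lo <- pmax(GenomicRanges::start(bl), s1) - exon$start
    hi <- pmin(GenomicRanges::end(bl), exon$end) - exon$start
    keep <- on_ref & lo <= hi & hi >= 1L & lo <= L
    if (any(keep)) {
      d <- tabulate(lo[keep], L + 1L) - tabulate(hi[keep] + 1L, L + 1L)
    }
  }
  as.integer(cumsum(d)[seq_len(L)])
}

#' Maximum of positional counts
#'
#' The maxcounts summarization: an exon's expression is the maximum,
#' over its bases, of the per-base read coverage. An all-zero profile
#' gives 0.
#'
#' @param profile Integer vector from [coverage_profile()].
#' @return A single non-negative integer.
#' @export
maxcounts <- function(profile) {
  if (!length(profile)) return(0L)
  as.integer(max(profile))
}

#' Total read count of one exon
#'
#' The conventional summarization: the number of distinct alignment
#' records having at least one aligned base inside the exon. A record
#' overlapping by a single base counts fully; a record overlapping in
#' several blocks counts once; a record whose only overlap with the exon
#' is a CIGAR `N` gap does not count.
#'
#' @inheritParams coverage_profile
#' @return A single non-negative integer.
#' @export
totcounts <- function(exon, aln) {
  refs <- attr(aln, "references")
  if (!is.null(refs) && !(exon$chrom %in% names(refs)))
    stop("exon reference '", exon$chrom,
         "' is not a reference sequence of the alignment set")
  if (!nrow(aln)) return(0L)
  bl <- ref_blocks(aln)
  hit <- as.character(GenomicRanges::seqnames(bl)) == exon$chrom &
    GenomicRanges::start(bl) <= exon$end &
    GenomicRanges::end(bl) >= exon$start + 1L
  length(unique(bl$rec[hit]))
}

#' Summarize all exons of a library in one pass
#'
#' Computes maxcounts and totcounts for every exon against one
#' library's alignments. This is the workhorse behind
#' [build_count_matrix()].
#'
#' @param aln An `mc_alignments` table.
#' @param exons An `exon_table`.
#' @return `data.frame` with columns `exon_id`, `maxcounts`,
#'   `totcounts`.
#' @export
summarize_exon_counts <- function(aln, exons) {
  n_ex <- nrow(exons)
  mx <- integer(n_ex)
  tt <- integer(n_ex)
  if (nrow(aln)) {
    bl <- ref_blocks(aln)
    ex <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end))
    h <- GenomicRanges::findOverlaps(bl, ex, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(h)
    ei <- S4Vectors::subjectHits(h)
    if (length(qh)) {
      rec <- bl$rec[qh]
      # totcounts: distinct (record, exon) pairs
      key <- (as.numeric(rec) - 1) * n_ex + ei
      first <- !duplicated(key)
      tt <- tabulate(ei[first], n_ex)
      # maxcounts: clipped difference arrays per exon
      es <- GenomicRanges::start(ex)[ei]
      ee <- GenomicRanges::end(ex)[ei]
      lo <- pmax(GenomicRanges::start(bl)[qh], es) - es + 1L
      hi <- pmin(GenomicRanges::end(bl)[qh], ee) - es + 1L
      byex <- split(seq_along(ei), ei)
      for (k in seq_along(byex)) {
        i <- as.integer(names(byex)[k])
        j <- byex[[k]]
        L <- exons$length[i]
        d <- tabulate(lo[j], L + 1L) - tabulate(hi[j] + 1L, L + 1L)
        mx[i] <- max(cumsum(d)[seq_len(L)])
      }
    }
  }
  data.frame(exon_id = exons$exon_id, maxcounts = as.integer(mx),
             totcounts = as.integer(tt), stringsAsFactors = FALSE)
}

#' Build an exons-by-libraries count matrix
#'
#' Applies one summarization method to each library and assembles the
#' results into a matrix with exon ids as row names and library ids as
#' column names. Deterministic given its inputs.
#'
#' @param exons An `exon_table`.
#' @param libraries Named list; each element is either an
#'   `mc_alignments` table or a path to a SAM/BAM file.
#' @param method `"max"` for maxcounts or `"tot"` for totcounts.
#' @return Integer matrix, exons x libraries, with attribute
#'   `"method"`.
#' @export
build_count_matrix <- function(exons, libraries, method = c("max", "tot")) {
  method <- match.arg(method)
  if (is.null(names(libraries)))
    names(libraries) <- paste0("lib", seq_along(libraries))
  col <- if (method == "max") "maxcounts" else "totcounts"
  m <- matrix(0L, nrow = nrow(exons), ncol = length(libraries),
              dimnames = list(exons$exon_id, names(libraries)))
  for (j in seq_along(libraries)) {
    lib <- libraries[[j]]
    if (is.character(lib)) {
      if (!file.exists(lib))
        stop("cannot read library file: ", lib)
      lib <- read_alignments(lib)
    }
    m[, j] <- summarize_exon_counts(lib, exons)[[col]]
  }
  attr(m, "method") <- method
  m
}

#' Drop exons with low average counts
#'
#' Removes rows whose mean raw count across libraries is strictly below
#' `threshold` (a mean of exactly `threshold` is retained). When a
#' `groups` factor is supplied the mean is taken within each replicate
#' group and a row is kept only if every group mean reaches the
#' threshold, so downstream per-group analyses see a common exon set.
#'
#' @param m Count matrix (exons x libraries) of raw counts.
#' @param threshold Minimum mean count, default 0.5.
#' @param groups Optional factor of length `ncol(m)` labelling replicate
#'   groups.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(m, threshold = 0.5, groups = NULL) {
  if (is.null(groups)) {
    keep <- rowMeans(m) >= threshold
  } else {
    groups <- as.factor(groups)
    gm <- vapply(levels(groups), function(g)
      rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
    if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1L)
    keep <- apply(gm >= threshold, 1L, all)
  }
  m[keep, , drop = FALSE]
}
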