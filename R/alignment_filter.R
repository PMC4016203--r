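#' Similarity of an alignment to the reference
#'
#' Defined as `(aligned_len - NM) / aligned_len`, clamped to `[0, 1]`,
#' where `aligned_len` is the number of read bases aligned (CIGAR
#' `M`/`=`/`X`) and `NM` the edit distance. Soft-clipped bases were
#' never compared to the reference and are excluded from the
#' denominator.
#'
#' @param aln An `mc_alignments` table.
#' @return Numeric vector of per-record similarities in `[0, 1]`.
#' @export
alignment_similarity <- function(aln) {
  if (is.null(aln$nm) || anyNA(aln$nm))
    stop("edit distance (NM) missing: the similarity filter cannot be ",
         "silently skipped")
  alen <- aligned_length(aln$cigar)
  pmin(pmax((alen - aln$nm) / alen, 0), 1)
}

mate_key <- function(aln) {
  mate <- ifelse(bitwAnd(aln$flag, 128L) > 0L, 2L, 1L)
  paste0(aln$qname, "/", mate)
}

#' Filter multireads and low-similarity alignments
#'
#' Post-processing applied before counting: removes every record of any
#' multiread (a read reported at more than one mapping location) and
#' every record whose similarity to the reference is strictly below
#' `min_similarity` (a record at exactly the threshold is kept).
#' Multimapping is detected primarily from the `NH` tag; records flagged
#' secondary (0x100) or supplementary (0x800), and read ids occurring in
#' more than one record per mate, are treated as evidence of
#' multimapping as a fallback for files without the tag.
#'
#' Filtering is idempotent, and after it every surviving read id occurs
#' at most once per mate. Per-class removal tallies are attached as
#' attribute `"filter_stats"` and reported via [message()].
#'
#' @param aln An `mc_alignments` table.
#' @param min_similarity Similarity threshold, default 0.97; records
#'   with similarity strictly lower are discarded. `NULL` skips the
#'   similarity filter.
#' @param drop_multireads Remove all records of multimapping reads
#'   (default `TRUE`).
#' @param verbose Emit a log line per removal class (default `TRUE`).
#' @return The filtered `mc_alignments` table (a subset of the input
#'   rows) with attribute `"filter_stats"`.
#' @export
filter_alignments <- function(aln, min_similarity = 0.97,
                              drop_multireads = TRUE, verbose = TRUE) {
  n_in <- nrow(aln)
  n_multi <- 0L
  if (drop_multireads && n_in) {
    key <- mate_key(aln)
    flagged <- (!is.na(aln$nh) & aln$nh > 1L) |
      bitwAnd(aln$flag, 256L) > 0L |
      bitwAnd(aln$flag, 2048L) > 0L
    multi_keys <- unique(c(key[flagged],
                           key[duplicated(key)]))
    drop <- key %in% multi_keys
    n_multi <- sum(drop)
    aln <- aln[!drop, , drop = FALSE]
  }
  n_lowsim <- 0L
  if (!is.null(min_similarity) && nrow(aln)) {
    sim <- alignment_similarity(aln)
    drop <- sim < min_similarity
    n_lowsim <- sum(drop)
    aln <- aln[!drop, , drop = FALSE]
  }
  stats <- c(input = n_in, multiread = n_multi,
             low_similarity = n_lowsim, output = nrow(aln))
  if (verbose) {
    message(sprintf("alignment filter: %d records in, %d multiread, %d low-similarity, %d out",
                    stats[["input"]], stats[["multiread"]],
                    stats[["low_similarity"]], stats[["output"]]))
  }
  attr(aln, "filter_stats") <- stats
  aln
}
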