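#' Read alignments from a SAM or BAM file
#'
#' Loads mapped alignment records into a flat table carrying the fields
#' the counting and filtering steps need: read id, flag, reference,
#' 1-based leftmost position, CIGAR, the `NM` edit distance and the `NH`
#' number of reported mapping locations (both `NA` when the file does
#' not carry the tag). SAM input is converted on the fly with
#' [Rsamtools::asBam()].
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A `data.frame` of class `mc_alignments` with columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `nm`, `nh`, plus the
#'   optional `seq` and `qual`. The set of reference sequences declared
#'   in the header is attached as attribute `"references"` (named
#'   integer vector of lengths).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("NM", "NH")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  mapped <- !is.na(res$pos)
  aln <- data.frame(
    qname = res$qname[mapped],
    flag = res$flag[mapped],
    rname = as.character(res$rname[mapped]),
    pos = res$pos[mapped],
    mapq = res$mapq[mapped],
    cigar = res$cigar[mapped],
    stringsAsFactors = FALSE
  )
  aln$nm <- if (is.null(res$tag$NM)) NA_integer_ else res$tag$NM[mapped]
  aln$nh <- if (is.null(res$tag$NH)) NA_integer_ else res$tag$NH[mapped]
  attr(aln, "references") <- hdr
  class(aln) <- c("mc_alignments", "data.frame")
  aln
}

#' Number of read bases aligned to the reference
#'
#' Sum of CIGAR `M`, `=` and `X` operation lengths per record. Soft- and
#' hard-clipped bases, insertions and skips contribute nothing.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of aligned lengths.
#' @export
aligned_length <- function(cigar) {
  tab <- GenomicAlignments::cigarOpTable(cigar)
  as.integer(tab[, "M"] + tab[, "="] + tab[, "X"])
}

#' Reference intervals covered by aligned bases
#'
#' Decomposes each record's CIGAR into the half-open reference blocks
#' covered by aligned bases (`M`/`=`/`X`); `N` and `D` operations open
#' gaps between blocks.
#'
#' @param aln An `mc_alignments` table.
#' @return A [GenomicRanges::GRanges] of blocks (1-based, closed, the
#'   Bioconductor convention) with a metadata column `rec` giving the
#'   originating record's row index in `aln`.
#' @keywords internal
ref_blocks <- function(aln) {
  irl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = c("M", "=", "X"), reduce.ranges = TRUE
  )
  n_per <- S4Vectors::elementNROWS(irl)
  ir <- unlist(irl, use.names = FALSE)
  GenomicRanges::GRanges(
    seqnames = rep(aln$rname, n_per),
    ranges = ir,
    rec = rep(seq_len(nrow(aln)), n_per)
  )
}

#' Write alignments as a SAM file
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header lines followed by one
#' record per row. `NM` and `NH` tags are written when present.
#'
#' @param aln An `mc_alignments` table.
#' @param references Named integer vector of reference sequence lengths
#'   (taken from `attr(aln, "references")` when omitted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, references = attr(aln, "references")) {
  if (is.null(references))
    stop("reference sequence lengths are required to write a SAM header")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(references),
                   as.integer(references)))
  seq <- if (!is.null(aln$seq)) aln$seq else rep("*", nrow(aln))
  qual <- if (!is.null(aln$qual)) aln$qual else rep("*", nrow(aln))
  mapq <- if (!is.null(aln$mapq)) aln$mapq else rep(255L, nrow(aln))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                 aln$qname, aln$flag, aln$rname, aln$pos, mapq,
                 aln$cigar, seq, qual)
  if (!is.null(aln$nm) && !anyNA(aln$nm))
    rec <- paste0(rec, sprintf("\tNM:i:%d", aln$nm))
  if (!is.null(aln$nh) && !anyNA(aln$nh))
    rec <- paste0(rec, sprintf("\tNH:i:%d", aln$nh))
  writeLines(c(hdr, rec), path)
  invisible(path)
}
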