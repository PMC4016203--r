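#' Load an exon annotation from a BED file
#'
#' Reads a BED3+ file into an exon table. BED coordinates (0-based,
#' half-open) are preserved verbatim, so a table written back with
#' [write_exons()] round-trips the input bit-exactly. When the optional
#' name column is absent, identifiers are synthesized as
#' `"chrom:start-end"`.
#'
#' @param path Path to a BED3/BED4/BED6 file. `track`, `browser` and `#`
#'   comment lines are skipped.
#' @return A `data.frame` of class `exon_table` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand` (`+`, `-` or `.`),
#'   `exon_id` and `length` (bp).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t110\te1", bed)
#' load_exons(bed)
#' @export
load_exons <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  recs <- vector("list", sum(keep))
  k <- 0L
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 3L)
      stop(sprintf("line %d: expected at least 3 BED columns, got %d",
                   ln, length(f)))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: non-integer coordinates '%s', '%s'",
                   ln, f[2], f[3]))
    if (end <= start)
      stop(sprintf("line %d: zero- or negative-length interval [%d, %d)",
                   ln, start, end))
    id <- if (length(f) >= 4L && nzchar(f[4])) f[4] else
      sprintf("%s:%d-%d", f[1], start, end)
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    k <- k + 1L
    recs[[k]] <- list(chrom = f[1], start = start, end = end,
                      strand = strand, exon_id = id)
  }
  ex <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    strand = vapply(recs, `[[`, "", "strand"),
    exon_id = vapply(recs, `[[`, "", "exon_id"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(ex$exon_id)
  if (any(dup))
    stop("duplicated exon identifiers: ",
         paste(unique(ex$exon_id[dup]), collapse = ", "))
  ex$length <- ex$end - ex$start
  class(ex) <- c("exon_table", "data.frame")
  ex
}

#' Write an exon table back to BED
#'
#' @param exons An `exon_table` from [load_exons()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exons <- function(exons, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     exons$chrom, exons$start, exons$end,
                     exons$exon_id, exons$strand), path)
  invisible(path)
}

#' GC fraction of nucleotide sequences
#'
#' Computes (G + C) / (A + C + G + T), case-insensitively. `N` bases are
#' excluded from both numerator and denominator so that masked runs do not
#' dilute the covariate; a sequence consisting only of `N` yields `NA`.
#'
#' @param sequence Character vector of nucleotide sequences over
#'   `{A,C,G,T,N}` (either case), or a [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @examples
#' compute_gc(c("GGCC", "AATT", "ACGTN"))
#' @export
compute_gc <- function(sequence) {
  if (!methods::is(sequence, "DNAStringSet")) {
    sequence <- as.character(sequence)
    if (any(!nzchar(sequence)))
      stop("empty sequence")
    bad <- grepl("[^ACGTNacgtn]", sequence)
    if (any(bad))
      stop("sequence contains characters outside {A,C,G,T,N}: ",
           sequence[which(bad)[1]])
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  }
  if (any(Biostrings::width(sequence) == 0L))
    stop("empty sequence")
  af <- Biostrings::alphabetFrequency(sequence, baseOnly = TRUE)
  gc <- af[, "G"] + af[, "C"]
  acgt <- gc + af[, "A"] + af[, "T"]
  ifelse(acgt > 0L, gc / acgt, NA_real_)
}

#' Annotate exons with GC content from a reference FASTA
#'
#' Extracts each exon's sequence from the reference and fills a `gc`
#' column via [compute_gc()].
#'
#' @param exons An `exon_table`.
#' @param reference Path to a FASTA file, or a [Biostrings::DNAStringSet]
#'   whose names cover all `exons$chrom`.
#' @return The exon table with an additional numeric `gc` column.
#' @export
add_gc <- function(exons, reference) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  missing_chrom <- setdiff(unique(exons$chrom), names(reference))
  if (length(missing_chrom))
    stop("reference is missing sequences: ",
         paste(missing_chrom, collapse = ", "))
  gc <- numeric(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    s <- Biostrings::subseq(reference[[exons$chrom[i]]],
                            start = exons$start[i] + 1L,
                            end = exons$end[i])
    gc[i] <- compute_gc(Biostrings::DNAStringSet(s))
  }
  exons$gc <- gc
  exons
}
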