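#' Read a FASTQ file into a data frame
#'
#' Thin wrapper around [ShortRead::readFastq()] returning plain character
#' columns, convenient for record-level trimming and re-mating. Qualities
#' are Sanger Phred+33 encoded.
#'
#' @param path FASTQ file path (uncompressed or gzip).
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  fq <- ShortRead::readFastq(path)
  data.frame(
    id = as.character(ShortRead::id(fq)),
    seq = as.character(ShortRead::sread(fq)),
    qual = as.character(Biostrings::quality(Biostrings::quality(fq))),
    stringsAsFactors = FALSE
  )
}

#' Write FASTQ records
#'
#' @param reads `data.frame` with columns `id`, `seq`, `qual`
#'   (Phred+33 quality strings).
#' @param path Output path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  out <- character(4L * n)
  if (n) {
    idx <- 4L * (seq_len(n) - 1L)
    out[idx + 1L] <- paste0("@", reads$id)
    out[idx + 2L] <- reads$seq
    out[idx + 3L] <- "+"
    out[idx + 4L] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

phred_values <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Trim low-quality read ends
#'
#' Removes the maximal run of consecutive bases with Phred quality below
#' `qmin` from the 5' end and from the 3' end. Interior low-quality bases
#' are kept. The result may be empty; trimming is idempotent.
#'
#' @param seq Nucleotide string.
#' @param qual Phred+33 quality string of the same length.
#' @param qmin Quality threshold; bases with quality `< qmin` at either
#'   end are clipped. Default 20.
#' @return List with elements `seq` and `qual` (possibly empty strings).
#' @examples
#' trim_read("ACGTT", rawToChar(as.raw(c(63, 63, 63, 52, 51))), qmin = 20)
#' @export
trim_read <- function(seq, qual, qmin = 20) {
  if (nchar(seq) != nchar(qual))
    stop("sequence and quality lengths differ")
  q <- utf8ToInt(qual) - 33L
  ok <- which(q >= qmin)
  if (!length(ok))
    return(list(seq = "", qual = ""))
  list(seq = substr(seq, ok[1], ok[length(ok)]),
       qual = substr(qual, ok[1], ok[length(ok)]))
}

#' Minimum-length filter for trimmed reads
#'
#' Discards reads strictly shorter than `minlen`: a read of exactly
#' `minlen` bases is kept.
#'
#' @param lengths Integer vector of post-trimming read lengths.
#' @param minlen Minimum length in bp, default 33.
#' @return Logical vector: `TRUE` for reads to keep.
#' @export
filter_length <- function(lengths, minlen = 33) {
  lengths >= minlen
}

strip_mate_suffix <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

trim_frame <- function(reads, qmin) {
  for (i in seq_len(nrow(reads))) {
    tr <- trim_read(reads$seq[i], reads$qual[i], qmin)
    reads$seq[i] <- tr$seq
    reads$qual[i] <- tr$qual
  }
  reads
}

#' Re-mate paired FASTQ files after trimming and length filtering
#'
#' Applies end trimming ([trim_read()]) and the minimum-length filter
#' ([filter_length()]) to both mates of each pair. Pairs in which both
#' mates survive are retained with order correspondence restored; pairs
#' in which exactly one mate survives contribute that mate to the
#' singleton set; pairs in which neither survives are dropped. Every
#' input read appears in at most one output set, and
#' `2 * pairs_out + singletons + discarded = reads_in`.
#'
#' @param fastq1,fastq2 Paths to the two mate files. Records must
#'   correspond by order once mate suffixes (`/1`, `/2`, or a
#'   whitespace-delimited tail) are stripped.
#' @param qmin Phred threshold for end trimming (default 20).
#' @param minlen Minimum post-trimming length in bp (default 33).
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_1.fastq`, `<prefix>_2.fastq` and
#'   `<prefix>_singletons.fastq`.
#' @return List with elements `pairs` (list of data frames `r1`, `r2`),
#'   `singletons` (data frame) and `stats` (named integer vector with
#'   `reads_in`, `pairs_out`, `singletons`, `discarded`).
#' @export
remate <- function(fastq1, fastq2, qmin = 20, minlen = 33,
                   out_prefix = NULL) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2))
    stop("mate files differ in record count (", nrow(r1), " vs ",
         nrow(r2), ")")
  k1 <- strip_mate_suffix(r1$id)
  k2 <- strip_mate_suffix(r2$id)
  bad <- which(k1 != k2)
  if (length(bad))
    stop("mate pairing cannot be established for read id '", k1[bad[1]],
         "' (record ", bad[1], ")")
  n_in <- 2L * nrow(r1)
  r1 <- trim_frame(r1, qmin)
  r2 <- trim_frame(r2, qmin)
  keep1 <- filter_length(nchar(r1$seq), minlen)
  keep2 <- filter_length(nchar(r2$seq), minlen)
  both <- keep1 & keep2
  only1 <- keep1 & !keep2
  only2 <- keep2 & !keep1
  singles <- rbind(r1[only1, , drop = FALSE], r2[only2, , drop = FALSE])
  res <- list(
    pairs = list(r1 = r1[both, , drop = FALSE],
                 r2 = r2[both, , drop = FALSE]),
    singletons = singles,
    stats = c(reads_in = n_in,
              pairs_out = sum(both),
              singletons = nrow(singles),
              discarded = n_in - 2L * sum(both) - nrow(singles))
  )
  if (!is.null(out_prefix)) {
    write_fastq(res$pairs$r1, paste0(out_prefix, "_1.fastq"))
    write_fastq(res$pairs$r2, paste0(out_prefix, "_2.fastq"))
    write_fastq(res$singletons, paste0(out_prefix, "_singletons.fastq"))
  }
  res
}
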