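# Independent brute-force oracles and random fixture generators.
# The oracles deliberately share no code with the package: coverage is
# accumulated per base by walking the CIGAR string, and TMM is evaluated
# as a literal step-by-step transcription of the formula.

.fixtures <- new.env(parent = emptyenv())

# reference positions (1-based) covered by aligned bases of one record
oracle_covered_positions <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  covered <- integer(0)
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    o <- sub("^\\d+", "", op)
    if (o %in% c("M", "=", "X")) {
      covered <- c(covered, seq.int(ref, ref + n - 1L))
      ref <- ref + n
    } else if (o %in% c("D", "N")) {
      ref <- ref + n
    } # I, S, H, P consume no reference
  }
  covered
}

# per-base pileup of one exon by naive per-position increments
oracle_counts <- function(exon, aln) {
  L <- exon$end - exon$start
  prof <- integer(L)
  tot <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$rname[i] != exon$chrom) next
    cov <- oracle_covered_positions(aln$cigar[i], aln$pos[i])
    inside <- cov[cov >= exon$start + 1L & cov <= exon$end]
    if (length(inside)) {
      tot <- tot + 1L
      for (p in inside) {
        q <- p - exon$start
        prof[q] <- prof[q] + 1L
      }
    }
  }
  list(profile = prof, max = if (L > 0L) max(prof) else 0L, tot = tot)
}

rand_cigar <- function() {
  parts <- character(0)
  if (stats::runif(1) < 0.2)
    parts <- c(parts, paste0(sample(1:5, 1), "S"))
  nblk <- sample(1:3, 1)
  for (b in seq_len(nblk)) {
    parts <- c(parts, paste0(sample(5:40, 1), "M"))
    if (b < nblk)
      parts <- c(parts, paste0(sample(1:50, 1),
                               sample(c("N", "D", "I"), 1)))
  }
  if (stats::runif(1) < 0.2)
    parts <- c(parts, paste0(sample(1:5, 1), "S"))
  paste(parts, collapse = "")
}

rand_alignments <- function(n_reads, chroms = "c1", chrom_len = 3000L) {
  df <- data.frame(
    qname = sprintf("r%05d", seq_len(n_reads)),
    flag = 0L,
    rname = sample(chroms, n_reads, replace = TRUE),
    pos = sample.int(max(chrom_len - 300L, 1L), n_reads, replace = TRUE),
    mapq = 50L,
    cigar = vapply(seq_len(n_reads), function(i) rand_cigar(), ""),
    nm = 0L, nh = 1L,
    stringsAsFactors = FALSE
  )
  attr(df, "references") <- stats::setNames(
    rep(chrom_len, length(chroms)), chroms)
  class(df) <- c("mc_alignments", "data.frame")
  df
}

rand_exons <- function(n, chroms = "c1", chrom_len = 3000L,
                       max_len = 800L) {
  start <- sample.int(chrom_len - max_len - 1L, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  ex <- data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len, strand = ".",
    exon_id = sprintf("e%03d", seq_len(n)), length = len,
    stringsAsFactors = FALSE
  )
  class(ex) <- c("exon_table", "data.frame")
  ex
}

# literal spreadsheet-style evaluation of the TMM factor formula
tmm_oracle <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  N <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / N
  r <- which.min(abs(uq - mean(uq)))
  fs <- numeric(ncol(counts))
  for (k in seq_len(ncol(counts))) {
    y <- counts[, k]
    yr <- counts[, r]
    use <- y > 0 & yr > 0
    M <- log2((y[use] / N[k]) / (yr[use] / N[r]))
    A <- 0.5 * log2((y[use] / N[k]) * (yr[use] / N[r]))
    w <- (N[k] - y[use]) / (N[k] * y[use]) +
      (N[r] - yr[use]) / (N[r] * yr[use])
    if (max(abs(M)) < 1e-6) {
      fs[k] <- 1
      next
    }
    n <- length(M)
    keep <- rank(M) >= floor(n * trim_m) + 1 &
      rank(M) <= n - floor(n * trim_m) &
      rank(A) >= floor(n * trim_a) + 1 &
      rank(A) <= n - floor(n * trim_a)
    fs[k] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  fs <- fs / exp(mean(log(fs)))
  names(fs) <- colnames(counts)
  fs
}

qstring <- function(q) intToUtf8(q + 33L)

# the length-bias study conditions, computed once and shared by the
# tests that look at the same fixture (raw-count bias and its removal
# by within-lane full-quantile normalization)
bias_fixture <- function() {
  if (!is.null(.fixtures$bias)) return(.fixtures$bias)
  cfg <- sim_config(seed = 1, n_exons = 2000, read_length = 50,
                    length_meanlog = log(300), length_sdlog = 0.9,
                    length_range = c(50, 5000), expr_sdlog = 1.8,
                    preference_k = Inf, three_prime_decay = Inf,
                    n_replicates = 2)
  truth <- simulate_truth(cfg, with_sequences = FALSE)
  ns <- truth$exons$length - cfg$read_length + 1L
  depth <- round(sum(truth$expression * ns))  # one read per start per unit expression
  libs <- lapply(1:2, function(r)
    simulate_library(truth, replicate_seed = cfg$seed + r,
                     lib_id = sprintf("rep%d", r), depth = depth))
  names(libs) <- c("rep1", "rep2")
  .fixtures$bias <- list(
    truth = truth,
    mx = build_count_matrix(truth$exons, libs, "max"),
    tt = build_count_matrix(truth$exons, libs, "tot")
  )
  .fixtures$bias
}
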