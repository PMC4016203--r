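#' Simulation configuration
#'
#' Collects the knobs of the synthetic-read generator. The generator
#' emulates the statistical structure of real exon-level RNA-seq data:
#' exons of log-normal length and beta-distributed GC content on a
#' pseudo-chromosome, log-normal expression spanning several orders of
#' magnitude, reads placed with a reproducible non-uniform positional
#' preference (including an exponential coverage drop toward the 3'
#' end), multireads and mismatch-bearing alignments.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_exons Number of exons.
#' @param read_length Read length in bp.
#' @param depth Expected total reads per library.
#' @param length_meanlog,length_sdlog Log-normal exon length parameters
#'   (bp).
#' @param length_range Exon lengths are clamped to this range (bp).
#' @param gc_shape1,gc_shape2 Beta parameters of per-exon GC content.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters
#'   (arbitrary units).
#' @param preference_k Gamma shape of the positional sequencing
#'   preference; `Inf` gives uniform coverage, small values (e.g. 0.5)
#'   highly skewed coverage.
#' @param preference_block Correlation length of the preference in bp:
#'   priming efficiency is drawn once per block of this size, so
#'   coverage varies at scales coarser than a read, as observed along
#'   real single-isoform transcripts.
#' @param three_prime_decay e-folding distance (bp) of the exponential
#'   coverage decay toward the 3' end; `Inf` disables it.
#' @param multiread_fraction Fraction of reads emitted with a second
#'   mapping record.
#' @param mismatch_rate Per-base substitution rate.
#' @param lowsim_fraction Fraction of reads injected with enough
#'   mismatches to fall below 97% similarity to the reference.
#' @param n_replicates Replicate libraries per group.
#' @param spacer Gap in bp between consecutive exons on the
#'   pseudo-chromosome.
#' @param base_quality Phred quality written for simulated bases.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_exons = 200L, read_length = 50L,
                       depth = 1e5, length_meanlog = log(300),
                       length_sdlog = 0.9, length_range = c(50L, 5000L),
                       gc_shape1 = 9, gc_shape2 = 11,
                       expr_meanlog = 0, expr_sdlog = 1.8,
                       preference_k = 1, preference_block = NULL,
                       three_prime_decay = 500,
                       multiread_fraction = 0, mismatch_rate = 0.002,
                       lowsim_fraction = 0, n_replicates = 2L,
                       spacer = 100L, base_quality = 40L) {
  if (is.null(preference_block)) preference_block <- 2L * read_length
  cfg <- list(seed = as.integer(seed), n_exons = as.integer(n_exons),
              read_length = as.integer(read_length), depth = depth,
              length_meanlog = length_meanlog,
              length_sdlog = length_sdlog,
              length_range = as.integer(length_range),
              gc_shape1 = gc_shape1, gc_shape2 = gc_shape2,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              preference_k = preference_k,
              preference_block = as.integer(preference_block),
              three_prime_decay = three_prime_decay,
              multiread_fraction = multiread_fraction,
              mismatch_rate = mismatch_rate,
              lowsim_fraction = lowsim_fraction,
              n_replicates = as.integer(n_replicates),
              spacer = as.integer(spacer),
              base_quality = as.integer(base_quality))
  stopifnot(cfg$n_exons >= 1, cfg$read_length >= 1, cfg$depth >= 0,
            cfg$length_range[1] >= cfg$read_length ||
              cfg$length_range[1] >= 1,
            cfg$preference_k > 0, cfg$preference_block >= 1,
            cfg$three_prime_decay > 0,
            cfg$multiread_fraction >= 0, cfg$multiread_fraction <= 1,
            cfg$mismatch_rate >= 0, cfg$mismatch_rate <= 1,
            cfg$lowsim_fraction >= 0, cfg$lowsim_fraction <= 1,
            cfg$n_replicates >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Positional sequencing preference of one transcript
#'
#' Per-start-position sampling weights modelling non-random priming:
#' Gamma(k, 1/k) efficiencies (mean 1) are drawn once per block of
#' `block` bp and held constant within a block, then multiplied by an
#' exponential decay toward the 3' end (e-folding distance `decay` bp,
#' over a window covering the last `3 * decay` bp). Weights are
#' normalized to sum 1; the overall priming efficiency of the
#' transcript, mean(raw)/max(raw) -- the read yield relative to a
#' transcript sequenced everywhere at its own peak efficiency -- is
#' attached as attribute `"efficiency"`. Patterns are reproducible:
#' the same seed yields the identical vector, and the same weights are
#' shared by all replicate libraries of an experiment.
#'
#' @param length Transcript length in bp (at least `read_length`).
#' @param k Gamma shape; `Inf` gives uniform weights.
#' @param decay 3'-decay e-folding distance in bp; `Inf` disables it.
#' @param read_length Read length in bp.
#' @param block Preference correlation length in bp (default twice the
#'   read length).
#' @param seed Optional seed; when `NULL` the current RNG stream is
#'   consumed.
#' @return Numeric weight vector of length `length - read_length + 1`
#'   summing to 1, with attribute `"efficiency"` in `(0, 1]`.
#' @export
simulate_preference <- function(length, k, decay, read_length,
                                block = 2L * read_length, seed = NULL) {
  if (length < read_length)
    stop("transcript length (", length, ") is shorter than the read ",
         "length (", read_length, ")")
  if (!is.null(seed)) set.seed(seed)
  ns <- length - read_length + 1L
  n_blocks <- ceiling(ns / block)
  g <- if (is.finite(k)) stats::rgamma(n_blocks, shape = k, scale = 1 / k)
       else rep(1, n_blocks)
  s <- g[ceiling(seq_len(ns) / block)]
  if (is.finite(decay)) {
    w_start <- ns - min(ns, round(3 * decay))
    d <- pmax(0, seq_len(ns) - w_start)
    s <- s * exp(-d / decay)
  }
  if (max(s) <= 0) s <- rep(1, ns)
  w <- s / sum(s)
  attr(w, "efficiency") <- mean(s) / max(s)
  w
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Ground truth of a simulated experiment
#'
#' Draws the per-exon quantities that stay fixed across replicate
#' libraries: exon lengths, GC contents, expression levels, positional
#' preference weights, and (optionally) the pseudo-chromosome sequence
#' with exons laid out `spacer` bp apart.
#'
#' @param config A [sim_config()].
#' @param with_sequences Also generate reference sequence (needed to
#'   emit FASTA/FASTQ and for GC diagnostics). Statistical draws are
#'   unaffected by this switch.
#' @return Object of class `mc_sim_truth`: list with `exons` (an
#'   `exon_table`, including realized `gc` when sequences are
#'   generated), `reference` (a [Biostrings::DNAStringSet] or `NULL`),
#'   `expression` (named), `weights` (named list, each with an
#'   `"efficiency"` attribute), and `config`.
#' @export
simulate_truth <- function(config, with_sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_exons
  L <- pmin(pmax(round(stats::rlnorm(n, config$length_meanlog,
                                     config$length_sdlog)),
                 max(config$length_range[1], config$read_length)),
            config$length_range[2])
  gc <- stats::rbeta(n, config$gc_shape1, config$gc_shape2)
  expr <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  weights <- lapply(seq_len(n), function(i)
    simulate_preference(L[i], config$preference_k,
                        config$three_prime_decay, config$read_length,
                        config$preference_block))
  ids <- sprintf("exon%04d", seq_len(n))
  names(weights) <- ids
  names(expr) <- ids
  start <- config$spacer +
    cumsum(c(0L, L[-n] + config$spacer))
  exons <- data.frame(chrom = "sim1", start = as.integer(start),
                      end = as.integer(start + L), strand = "+",
                      exon_id = ids, length = as.integer(L),
                      stringsAsFactors = FALSE)
  class(exons) <- c("exon_table", "data.frame")
  reference <- NULL
  if (with_sequences) {
    chrom_len <- start[n] + L[n] + config$spacer
    base <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    for (i in seq_len(n)) {
      seq_i <- strsplit(rand_seq(L[i], gc[i]), "")[[1]]
      base[(start[i] + 1L):(start[i] + L[i])] <- seq_i
    }
    reference <- Biostrings::DNAStringSet(paste(base, collapse = ""))
    names(reference) <- "sim1"
    exons$gc <- compute_gc(Biostrings::DNAStringSet(
      substring(as.character(reference[[1]]), exons$start + 1L,
                exons$end)))
  }
  structure(list(exons = exons, reference = reference,
                 expression = expr, weights = weights, config = config),
            class = "mc_sim_truth")
}

#' Panel of synthetic spike-in transcripts
#'
#' Builds `n` single-isoform transcripts with known concentrations,
#' log-uniformly spaced over `conc_range` (consecutive log-ratios are
#' equal), each on its own reference sequence with a positional
#' preference drawn under the configuration. The returned object plays
#' the role of an experiment ground truth whose expression equals the
#' concentration, so spike-in accuracy can be evaluated against it.
#'
#' @param n Number of spike-ins (at least 2; equal `conc_range` bounds
#'   give an equal-concentration pair for discrepancy experiments).
#' @param conc_range Concentration range (arbitrary units, e.g.
#'   nmol/ul).
#' @param config A [sim_config()]; GC and preference parameters are
#'   taken from it.
#' @param with_sequences Generate transcript sequences (FASTA support).
#' @param length_range Transcript length bounds in bp. Spike-in
#'   standards are full transcripts, not exons, so the default mirrors
#'   the 250-2000 bp span of the ERCC panel rather than the
#'   configuration's exon lengths.
#' @return An `mc_sim_truth` with an additional element
#'   `concentrations` (data frame `id`, `concentration`).
#' @export
make_spikein_panel <- function(n, conc_range, config,
                               with_sequences = TRUE,
                               length_range = c(250L, 2000L)) {
  stopifnot(inherits(config, "sim_config"), n >= 2)
  set.seed(config$seed)
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n)
  ids <- sprintf("spike%03d", seq_len(n))
  L <- pmin(pmax(round(stats::rlnorm(n, config$length_meanlog,
                                     config$length_sdlog)),
                 max(length_range[1], config$read_length)),
            length_range[2])
  gc <- stats::rbeta(n, config$gc_shape1, config$gc_shape2)
  weights <- lapply(seq_len(n), function(i)
    simulate_preference(L[i], config$preference_k,
                        config$three_prime_decay, config$read_length,
                        config$preference_block))
  names(weights) <- ids
  conc <- stats::setNames(conc, ids)
  exons <- data.frame(chrom = ids, start = 0L, end = as.integer(L),
                      strand = "+", exon_id = ids,
                      length = as.integer(L), stringsAsFactors = FALSE)
  class(exons) <- c("exon_table", "data.frame")
  reference <- NULL
  if (with_sequences) {
    reference <- Biostrings::DNAStringSet(
      vapply(seq_len(n), function(i) rand_seq(L[i], gc[i]), ""))
    names(reference) <- ids
    exons$gc <- compute_gc(reference)
  }
  structure(list(exons = exons, reference = reference,
                 expression = conc, weights = weights, config = config,
                 concentrations = data.frame(
                   id = ids, concentration = as.numeric(conc),
                   stringsAsFactors = FALSE)),
            class = "mc_sim_truth")
}

#' Simulate one replicate library
#'
#' Draws reads per exon as Poisson with expectation proportional to
#' expression x valid start positions x priming efficiency (so skewed
#' preference reduces total yield, as along real transcripts, while
#' peak coverage tracks concentration), places read starts from the
#' exon's shared preference weights, and injects mismatches and
#' multireads. SAM fields (`NM`, `NH`, secondary flags) are consistent
#' with the injected events.
#'
#' @param truth An `mc_sim_truth`.
#' @param replicate_seed Seed for this library's draws (preference
#'   weights stay those of `truth`, shared across replicates).
#' @param lib_id Library identifier used in read names.
#' @param depth Expected total reads; defaults to the configuration's.
#' @param emit_sequences Generate read sequences and qualities
#'   (required to write SAM with bases, or FASTQ).
#' @return An `mc_alignments` table (with `seq`/`qual` columns when
#'   `emit_sequences`), reference lengths attached as attribute
#'   `"references"`.
#' @export
simulate_library <- function(truth, replicate_seed, lib_id = "lib1",
                             depth = NULL, emit_sequences = FALSE) {
  stopifnot(inherits(truth, "mc_sim_truth"))
  cfg <- truth$config
  if (is.null(depth)) depth <- cfg$depth
  if (emit_sequences && is.null(truth$reference))
    stop("truth was generated without sequences")
  rl <- cfg$read_length
  ex <- truth$exons
  n <- nrow(ex)
  ns <- ex$length - rl + 1L
  eff <- vapply(truth$weights, attr, numeric(1), "efficiency")
  yield <- truth$expression * ns * eff
  lambda <- if (sum(yield) > 0) depth * yield / sum(yield) else
    rep(0, n)
  set.seed(replicate_seed)
  n_reads <- stats::rpois(n, lambda)
  total <- sum(n_reads)
  pos <- integer(total)
  rname <- character(total)
  at <- 0L
  for (i in seq_len(n)) {
    if (n_reads[i] == 0L) next
    st <- sample.int(ns[i], n_reads[i], replace = TRUE,
                     prob = truth$weights[[i]])
    idx <- at + seq_len(n_reads[i])
    pos[idx] <- ex$start[i] + st
    rname[idx] <- ex$chrom[i]
    at <- at + n_reads[i]
  }
  nm <- stats::rbinom(total, rl, cfg$mismatch_rate)
  if (cfg$lowsim_fraction > 0) {
    low <- stats::runif(total) < cfg$lowsim_fraction
    nm[low] <- pmax(nm[low], as.integer(floor(0.03 * rl)) + 1L)
  }
  nh <- rep(1L, total)
  flag <- rep(0L, total)
  sec <- logical(total)
  if (cfg$multiread_fraction > 0 && total) {
    sec <- stats::runif(total) < cfg$multiread_fraction
    nh[sec] <- 2L
  }
  aln <- data.frame(
    qname = if (total) paste0(lib_id, ".", seq_len(total)) else
      character(0),
    flag = flag, rname = rname, pos = pos,
    mapq = rep(50L, total),
    cigar = rep(paste0(rl, "M"), total), nm = nm, nh = nh,
    stringsAsFactors = FALSE
  )
  if (any(sec)) {
    tgt <- sample.int(n, sum(sec), replace = TRUE)
    st2 <- floor(stats::runif(sum(sec)) * ns[tgt]) + 1L
    aln2 <- aln[sec, , drop = FALSE]
    aln2$flag <- 256L
    aln2$rname <- ex$chrom[tgt]
    aln2$pos <- ex$start[tgt] + st2
    aln2$mapq <- 0L
    aln <- rbind(aln, aln2)
  }
  if (emit_sequences && nrow(aln)) {
    aln$seq <- extract_read_seqs(truth$reference, aln$rname, aln$pos,
                                 rl, aln$nm)
    aln$qual <- strrep(intToUtf8(cfg$base_quality + 33L), rl)
  }
  attr(aln, "references") <- stats::setNames(
    if (is.null(truth$reference)) {
      # lengths are known from the layout even without sequences
      vapply(unique(ex$chrom), function(ch)
        max(ex$end[ex$chrom == ch]) + cfg$spacer, numeric(1))
    } else Biostrings::width(truth$reference),
    if (is.null(truth$reference)) unique(ex$chrom) else
      names(truth$reference))
  class(aln) <- c("mc_alignments", "data.frame")
  aln
}

extract_read_seqs <- function(reference, rname, pos, rl, nm) {
  out <- character(length(pos))
  bases <- c("A", "C", "G", "T")
  for (ch in unique(rname)) {
    idx <- which(rname == ch)
    out[idx] <- substring(as.character(reference[[ch]]), pos[idx],
                          pos[idx] + rl - 1L)
  }
  mm <- which(nm > 0L)
  for (i in mm) {
    p <- sample.int(rl, min(nm[i], rl))
    s <- strsplit(out[i], "")[[1]]
    for (q in p) s[q] <- sample(setdiff(bases, s[q]), 1L)
    out[i] <- paste(s, collapse = "")
  }
  out
}

#' Write a simulated library to SAM and FASTQ
#'
#' @param aln An `mc_alignments` table from [simulate_library()] with
#'   sequences.
#' @param dir Output directory.
#' @param name File stem; writes `<name>.sam` and `<name>.fastq` (the
#'   FASTQ holds one record per primary alignment).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_sim_library <- function(aln, dir, name) {
  if (is.null(aln$seq))
    stop("library was simulated without sequences")
  sam <- file.path(dir, paste0(name, ".sam"))
  fastq <- file.path(dir, paste0(name, ".fastq"))
  write_sam(aln, sam)
  prim <- bitwAnd(aln$flag, 256L) == 0L & bitwAnd(aln$flag, 2048L) == 0L
  write_fastq(data.frame(id = aln$qname[prim], seq = aln$seq[prim],
                         qual = aln$qual[prim],
                         stringsAsFactors = FALSE), fastq)
  invisible(c(sam = sam, fastq = fastq))
}

#' Generate a complete fixture set on disk
#'
#' Runs [simulate_truth()] and [simulate_library()] for each replicate
#' and writes reference FASTA, exon BED, ground-truth TSV and
#' per-replicate SAM/FASTQ into `out_dir`. Identical configurations
#' produce byte-identical outputs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `truth` and `files` (named paths).
#' @export
simulate_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config, with_sequences = TRUE)
  fa <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(truth$reference, fa)
  bed <- file.path(out_dir, "exons.bed")
  write_exons(truth$exons, bed)
  gt <- file.path(out_dir, "ground_truth.tsv")
  eff <- vapply(truth$weights, attr, numeric(1), "efficiency")
  utils::write.table(
    data.frame(exon_id = truth$exons$exon_id,
               length = truth$exons$length, gc = truth$exons$gc,
               expression = as.numeric(truth$expression),
               efficiency = as.numeric(eff)),
    gt, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(reference = fa, exons = bed, ground_truth = gt)
  for (r in seq_len(config$n_replicates)) {
    name <- sprintf("rep%d", r)
    aln <- simulate_library(truth, replicate_seed = config$seed + r,
                            lib_id = name, emit_sequences = TRUE)
    paths <- write_sim_library(aln, out_dir, name)
    files <- c(files, stats::setNames(paths,
                                      paste0(name, "_", names(paths))))
  }
  invisible(list(truth = truth, files = files))
}
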