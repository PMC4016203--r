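#' Trimmed mean of M-values scaling factors
#'
#' Between-library scaling normalization robust to composition bias.
#' The reference library is the one whose upper quartile of
#' library-size-scaled counts is closest to the mean upper quartile.
#' For each library, exons with a zero count in either the library or
#' the reference are excluded; the log-ratio
#' `M = log2((y_k/N_k)/(y_r/N_r))` and average intensity
#' `A = 0.5 * log2((y_k/N_k) * (y_r/N_r))` are doubly trimmed
#' (`trim_m` on each tail of M, `trim_a` on each tail of A) and the
#' scaling factor is `2^` the weighted mean of the retained M values,
#' with inverse binomial asymptotic variances as weights. Factors are
#' rescaled so their geometric mean is 1, which makes them invariant to
#' multiplying any library by a positive constant.
#'
#' @param counts Raw count matrix (exons x libraries), at least two
#'   libraries.
#' @param trim_m Two-sided trim fraction on M, default 0.30.
#' @param trim_a Two-sided trim fraction on A, default 0.05.
#' @param lib_sizes Library sizes; defaults to the column sums. An
#'   already depth-corrected matrix can be re-estimated under equal
#'   sizes (the round trip then returns factors near 1).
#' @return Named numeric vector of positive factors (one per library)
#'   with attribute `"ref_library"`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("TMM requires at least two libraries")
  lib <- if (is.null(lib_sizes)) colSums(counts) else lib_sizes
  if (length(lib) != ncol(counts))
    stop("lib_sizes do not cover all libraries")
  if (any(colSums(counts) == 0))
    stop("library with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  uq <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
  ref <- if (stats::median(uq) < 1e-20)
    which.max(colSums(sqrt(counts))) else which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref_library") <- if (is.null(colnames(counts))) ref else
    colnames(counts)[ref]
  f
}

# one library against the reference; the weighted doubly-trimmed mean of M
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / w[keep], na.rm = TRUE) /
    sum(1 / w[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Scale a count matrix by size factors
#'
#' Divides each library by its effective size (scaling factor times
#' library total) and rescales by the geometric mean of the effective
#' sizes, so values stay on a count-like scale and the relative ordering
#' within each library is preserved.
#'
#' @param counts Count matrix (exons x libraries).
#' @param factors Named numeric vector from [tmm_factors()] covering all
#'   columns of `counts`.
#' @return Numeric matrix of normalized counts.
#' @export
apply_size_factors <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (!is.null(names(factors)) && !is.null(colnames(counts))) {
    missing_lib <- setdiff(colnames(counts), names(factors))
    if (length(missing_lib))
      stop("no scaling factor for library: ",
           paste(missing_lib, collapse = ", "))
    factors <- factors[colnames(counts)]
  } else if (length(factors) != ncol(counts)) {
    stop("factors do not cover all libraries")
  }
  eff <- factors * colSums(counts)
  sweep(counts, 2L, eff, "/") * exp(mean(log(eff)))
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM_ij = N_ij / (L_i/1e3 * N.j/1e6)` where `L_i` is the exon
#' length in bp and `N.j` the library total. Inputs are raw counts (not
#' scaled beforehand).
#'
#' @param counts Raw count matrix (exons x libraries).
#' @param lengths Exon lengths in bp, in row order (or named by exon
#'   id).
#' @return Numeric matrix of RPKM values.
#' @examples
#' m <- matrix(c(500, 19999500), 2, 1,
#'             dimnames = list(c("e1", "e2"), "l1"))  # N.j = 2e7
#' rpkm(m, lengths = c(2000, 1000))["e1", ]           # 12.5
#' @export
rpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("lengths do not cover all exons")
  if (any(lengths <= 0))
    stop("exon lengths must be positive")
  n_tot <- colSums(counts)
  if (any(n_tot == 0))
    stop("library with zero total count: ",
         paste(colnames(counts)[n_tot == 0], collapse = ", "))
  sweep(counts / (lengths / 1e3), 2L, n_tot / 1e6, "/")
}

# map one vector onto a sorted target profile; tied input values receive
# the mean of the normalized values their ranks span
quantile_map <- function(x, target) {
  out <- numeric(length(x))
  out[order(x)] <- target
  stats::ave(out, match(x, x), FUN = mean)
}

#' Between-lane full-quantile normalization
#'
#' Forces every library onto the common quantile profile obtained by
#' averaging order statistics across libraries: each library's sorted
#' values are replaced by the across-library mean of order statistics,
#' mapped back through the library's own ranks. Ranks within each
#' library, and the grand mean of the matrix, are preserved; in the
#' absence of ties all columns share an identical sorted vector
#' afterwards (tied values receive the mean of the normalized values
#' they span).
#'
#' @param counts Count matrix (exons x libraries), at least two
#'   libraries.
#' @return Numeric matrix of normalized values.
#' @export
fq_between_lane <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("between-lane normalization requires at least two libraries")
  target <- rowMeans(apply(counts, 2L, sort))
  out <- counts
  for (j in seq_len(ncol(counts)))
    out[, j] <- quantile_map(counts[, j], target)
  out
}

#' Within-lane full-quantile normalization over a covariate
#'
#' Removes the dependence of counts on a gene-specific covariate
#' (typically exon length) within each library. Exons are stratified
#' into `n_strata` equal-size groups by covariate rank; within the
#' library, each stratum's values are mapped onto the mean empirical
#' quantile profile across strata, so afterwards the count distribution
#' is identical across strata up to ties and unequal stratum sizes.
#'
#' @param counts Count matrix (exons x libraries).
#' @param covariate Numeric covariate per exon (row order of `counts`).
#' @param n_strata Number of covariate strata, default 10.
#' @return Numeric matrix of normalized values.
#' @export
fq_within_lane <- function(counts, covariate, n_strata = 10) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (length(covariate) != n)
    stop("covariate does not cover all exons")
  if (n_strata > n)
    stop("more strata (", n_strata, ") than exons (", n, ")")
  sizes <- rep(floor(n / n_strata), n_strata)
  extra <- n %% n_strata
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stratum <- integer(n)
  stratum[order(covariate)] <- rep(seq_len(n_strata), sizes)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    xs <- split(x, stratum)
    p <- numeric(n)
    for (s in seq_len(n_strata)) {
      idx <- stratum == s
      r <- rank(x[idx], ties.method = "average")
      n_s <- sum(idx)
      # (r-1)/(n-1) places each order statistic exactly on the type-7
      # quantile grid, so identical strata map onto themselves
      p[idx] <- if (n_s > 1L) (r - 1) / (n_s - 1) else 0.5
    }
    # mean empirical quantile profile across strata, evaluated at each
    # exon's within-stratum probability
    qmat <- vapply(xs, function(v)
      stats::quantile(v, probs = p, names = FALSE, type = 7), numeric(n))
    out[, j] <- rowMeans(qmat)
  }
  out
}
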