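#' Binned bias curve of counts against a covariate
#'
#' Sorts exons by the covariate, averages covariate and response in
#' consecutive bins of `bin_size` exons (the last bin may be smaller),
#' and fits a natural cubic spline through the bin means. The Spearman
#' correlation of the unbinned `(x, y)` pairs is reported as a scalar
#' bias score.
#'
#' @param x Per-exon covariate (e.g. log length or GC fraction).
#' @param y Per-exon response (e.g. mean log-count).
#' @param bin_size Exons per bin, default 5000.
#' @param rescale_x Affinely rescale the x axis to `[0, 1]` (used by the
#'   variance/CV curves to make different measures comparable).
#' @return Object of class `mc_binned_curve`: a list with `mean_x`,
#'   `mean_y`, `bin_bounds`, `n_bins`, `spearman` and `spline` (a
#'   function evaluable at arbitrary x).
#' @export
binned_bias_curve <- function(x, y, bin_size = 5000, rescale_x = FALSE) {
  if (length(x) != length(y))
    stop("x and y lengths differ")
  if (length(x) < 2L)
    stop("at least two points are required")
  sp <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(sp)) sp <- 0
  o <- order(x)
  bin <- ceiling(seq_along(o) / bin_size)
  mean_x <- as.numeric(tapply(x[o], bin, mean))
  mean_y <- as.numeric(tapply(y[o], bin, mean))
  xs <- x[o]
  cuts <- cumsum(tabulate(bin))
  bounds <- c(xs[1], xs[cuts])
  if (rescale_x) {
    rg <- range(x)
    scale01 <- function(v) if (diff(rg) > 0) (v - rg[1]) / diff(rg) else
      rep(0, length(v))
    mean_x <- scale01(mean_x)
    bounds <- scale01(bounds)
  }
  ux <- !duplicated(mean_x)
  spl <- if (sum(ux) >= 2L) {
    stats::splinefun(mean_x[ux], mean_y[ux], method = "natural")
  } else {
    const <- mean_y[1]
    function(v) rep(const, length(v))
  }
  structure(list(mean_x = mean_x, mean_y = mean_y, bin_bounds = bounds,
                 n_bins = length(mean_x), spearman = sp, spline = spl),
            class = "mc_binned_curve")
}

#' Concentration of counts on highly expressed exons
#'
#' Cumulative share of a library's counts carried by its most expressed
#' exons. Zero-count exons are excluded; counts are sorted in decreasing
#' order, and the reported percentages are the smallest fraction of
#' nonzero exons whose counts reach 50% and 90% of the library total.
#'
#' @param counts One library's count vector.
#' @return Object of class `mc_distribution_summary`: list with `curve`
#'   (data frame `pct_exons`, `pct_counts`), `pct_exons_at_50`,
#'   `pct_exons_at_90` and `n_nonzero`.
#' @examples
#' distribution_summary(c(50, 30, 20))$pct_exons_at_50  # 33.3
#' @export
distribution_summary <- function(counts) {
  nz <- counts[!is.na(counts) & counts > 0]
  if (!length(nz))
    stop("all counts are zero")
  s <- sort(nz, decreasing = TRUE)
  cum <- cumsum(s) / sum(s)
  n <- length(s)
  pct_at <- function(q) 100 * min(which(cum >= q - 1e-12)) / n
  structure(list(
    curve = data.frame(pct_exons = 100 * seq_len(n) / n,
                       pct_counts = 100 * cum),
    pct_exons_at_50 = pct_at(0.5),
    pct_exons_at_90 = pct_at(0.9),
    n_nonzero = n
  ), class = "mc_distribution_summary")
}

#' Variance and coefficient-of-variation curves across replicates
#'
#' For each exon of one replicate group, computes the mean and unbiased
#' variance of `log2(count + 1)` across replicates (variance curve) and
#' the raw-scale coefficient of variation, sd/mean (CV curve, against
#' the log of the mean raw count). Exons are binned by the x value and
#' bin means are splined; x axes are affinely rescaled to `[0, 1]` so
#' curves from different measures are comparable.
#'
#' @param m Count matrix restricted to one replicate group (at least two
#'   columns).
#' @param bin_size Exons per bin, default 5000.
#' @return List with elements `variance` and `cv`, each an
#'   `mc_binned_curve`.
#' @export
variance_cv_curves <- function(m, bin_size = 5000) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("variance requires at least two replicates")
  lm_ <- log2(m + 1)
  var_x <- rowMeans(lm_)
  var_y <- apply(lm_, 1L, stats::var)
  raw_mean <- rowMeans(m)
  keep <- raw_mean > 0
  cv_y <- apply(m[keep, , drop = FALSE], 1L, stats::sd) / raw_mean[keep]
  cv_x <- log2(raw_mean[keep] + 1)
  list(
    variance = binned_bias_curve(var_x, var_y, bin_size, rescale_x = TRUE),
    cv = binned_bias_curve(cv_x, cv_y, bin_size, rescale_x = TRUE)
  )
}

#' Accuracy of spike-in quantification
#'
#' Compares estimated spike-in abundances with their known
#' concentrations on the log-log scale: Pearson correlation (with the
#' standard t-transform two-sided p-value), the least-squares regression
#' line, and per-spike-in residuals.
#'
#' @param counts Named vector of per-spike-in mean counts (or
#'   normalized values); zero entries are dropped.
#' @param truth Data frame with columns `id` and `concentration`
#'   (positive, unique ids) covering the named counts.
#' @return List with `r`, `p_value`, `slope`, `intercept`, `residuals`
#'   (named), and `n`.
#' @export
spikein_accuracy <- function(counts, truth) {
  if (anyDuplicated(truth$id))
    stop("duplicate spike-in ids in the concentration table")
  if (any(truth$concentration <= 0))
    stop("spike-in concentrations must be positive")
  counts <- counts[!is.na(counts) & counts > 0]
  idx <- match(names(counts), truth$id)
  if (anyNA(idx))
    stop("concentration unknown for spike-in: ",
         paste(names(counts)[is.na(idx)], collapse = ", "))
  if (length(counts) < 3L)
    stop("at least 3 spike-ins with nonzero counts are required")
  lx <- log2(truth$concentration[idx])
  ly <- log2(counts)
  fit <- stats::lm(ly ~ lx)
  ct <- stats::cor.test(lx, ly)
  res <- stats::residuals(fit)
  names(res) <- names(counts)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = res, n = length(counts))
}

#' Discrepancy between two equal-concentration transcripts
#'
#' `delta = (x_a - x_b) / (x_a + x_b) * 100`, in percent. For two
#' transcripts of (nearly) equal true concentration an unbiased
#' summarization should give a delta close to zero; the statistic is
#' antisymmetric in its arguments and bounded in `[-100, 100]`.
#'
#' @param xa,xb Mean counts of the two transcripts (non-negative, not
#'   both zero).
#' @return Percent discrepancy.
#' @examples
#' delta_stat(139, 61)  # 39
#' @export
delta_stat <- function(xa, xb) {
  if (xa + xb <= 0)
    stop("both counts are zero: delta is undefined")
  (xa - xb) / (xa + xb) * 100
}

#' Sensitivity of counts to alignment filtering
#'
#' Relative variation between counts from the original and the filtered
#' alignment sets: `(X_orig - X_filt) / (X_orig + 1) * 100`; the `+ 1`
#' in the denominator avoids division by zero. Inputs are raw counts
#' (not normalized), so the direct impact of filtering on
#' summarization is measured.
#'
#' @param orig,filt Count matrices sharing row and column names.
#' @return List with `variation` (percent matrix) and `fraction_zero`
#'   (fraction of entries exactly 0%).
#' @examples
#' relative_variation(matrix(10), matrix(8))$variation  # 200/11
#' @export
relative_variation <- function(orig, filt) {
  orig <- as.matrix(orig)
  filt <- as.matrix(filt)
  if (!identical(dim(orig), dim(filt)) ||
      !identical(dimnames(orig), dimnames(filt)))
    stop("matrices do not share the same exon/library index")
  rv <- (orig - filt) / (orig + 1) * 100
  list(variation = rv, fraction_zero = mean(rv == 0))
}
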