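test_that("binned curves average covariate-sorted bins and score bias", {
  # constant response: flat spline, zero bias score
  bc <- binned_bias_curve(1:100, rep(3, 100), bin_size = 10)
  expect_equal(bc$n_bins, 10L)
  expect_equal(bc$mean_y, rep(3, 10))
  expect_equal(bc$spearman, 0)
  expect_equal(bc$spline(c(5, 50)), c(3, 3))
  # single bin degenerates to the bin mean point
  bc1 <- binned_bias_curve(1:10, 1:10, bin_size = 50)
  expect_equal(bc1$n_bins, 1L)
  expect_equal(bc1$mean_y, 5.5)
  expect_equal(bc1$spline(c(0, 99)), c(5.5, 5.5))
  expect_equal(bc1$spearman, 1)
  # last bin may be smaller; bin means are plain averages
  bc2 <- binned_bias_curve(1:10, (1:10)^2, bin_size = 4)
  expect_equal(bc2$mean_x, c(mean(1:4), mean(5:8), mean(9:10)))
  expect_equal(bc2$mean_y, c(mean((1:4)^2), mean((5:8)^2),
                             mean((9:10)^2)))
  # the spline interpolates the bin means
  expect_equal(bc2$spline(bc2$mean_x), bc2$mean_y)
  expect_error(binned_bias_curve(1, 1), "two points")
})

test_that("count concentration reports the top-share percentages", {
  ds <- distribution_summary(c(50, 30, 20))
  expect_equal(ds$pct_exons_at_50, 100 / 3, tolerance = 1e-9)
  ds2 <- distribution_summary(rep(4, 10))
  expect_equal(ds2$pct_exons_at_50, 50)
  ds3 <- distribution_summary(c(90, 5, 5))
  expect_equal(ds3$pct_exons_at_90, 100 / 3, tolerance = 1e-9)
  # zero-count exons are excluded from the denominator
  ds4 <- distribution_summary(c(50, 30, 20, 0, 0, 0))
  expect_equal(ds4$pct_exons_at_50, 100 / 3, tolerance = 1e-9)
  expect_error(distribution_summary(c(0, 0)), "zero")
  # monotone, concave cumulative curve ending at (100, 100)
  set.seed(3)
  ds5 <- distribution_summary(rpois(200, 10))
  expect_true(all(diff(ds5$curve$pct_counts) >= -1e-12))
  expect_true(all(diff(diff(ds5$curve$pct_counts)) <= 1e-9))
  expect_equal(ds5$curve$pct_counts[nrow(ds5$curve)], 100)
  expect_lte(ds5$pct_exons_at_50, ds5$pct_exons_at_90)
})

test_that("variance and CV curves summarize replicate dispersion", {
  # identical replicates: zero variance and CV everywhere
  m <- matrix(rep(c(4, 9, 25), 2), ncol = 2)
  vc <- variance_cv_curves(m, bin_size = 2)
  expect_true(all(vc$variance$mean_y == 0))
  expect_true(all(vc$cv$mean_y == 0))
  # replicates (2, 4): raw mean 3, variance 2, CV = sqrt(2)/3
  m2 <- matrix(c(2, 4), nrow = 1)
  m2 <- m2[rep(1, 6), ]
  vc2 <- variance_cv_curves(m2, bin_size = 6)
  expect_equal(vc2$cv$mean_y, sqrt(2) / 3, tolerance = 1e-12)
  expect_equal(vc2$variance$mean_y, stats::var(log2(c(2, 4) + 1)),
               tolerance = 1e-12)
  # the x axis is affinely rescaled to [0, 1]
  set.seed(9)
  m3 <- matrix(rpois(400, 20), ncol = 2)
  vc3 <- variance_cv_curves(m3, bin_size = 25)
  expect_gte(min(vc3$variance$bin_bounds), 0)
  expect_lte(max(vc3$variance$bin_bounds), 1)
  expect_equal(range(vc3$variance$bin_bounds), c(0, 1))
  expect_error(variance_cv_curves(matrix(1:3, ncol = 1)), "two replicates")
})

test_that("spike-in accuracy recovers exact log-log relationships", {
  truth <- data.frame(id = paste0("s", 1:6),
                      concentration = 10^(1:6))
  counts <- stats::setNames(5 * truth$concentration, truth$id)
  acc <- spikein_accuracy(counts, truth)
  expect_equal(acc$r, 1, tolerance = 1e-12)
  expect_equal(acc$slope, 1, tolerance = 1e-12)
  expect_true(all(abs(acc$residuals) < 1e-9))
  expect_lt(acc$p_value, 1e-6)
  # counts = concentration^2 gives slope 2 on the log-log scale
  acc2 <- spikein_accuracy(stats::setNames(truth$concentration^2,
                                           truth$id), truth)
  expect_equal(acc2$r, 1, tolerance = 1e-12)
  expect_equal(acc2$slope, 2, tolerance = 1e-12)
  expect_error(spikein_accuracy(counts[1:2], truth), "at least 3")
  expect_error(spikein_accuracy(stats::setNames(1:3, c("s1", "s2", "zz")),
                                truth), "zz")
})

test_that("the delta statistic measures relative discrepancy in percent", {
  expect_equal(delta_stat(7, 7), 0)
  expect_equal(delta_stat(139, 61), 39)
  expect_equal(delta_stat(7.06e-7, 7.08e-7), -100 / 707, tolerance = 1e-9)
  # antisymmetry
  set.seed(13)
  for (i in 1:20) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    expect_equal(delta_stat(a, b), -delta_stat(b, a))
    expect_lte(abs(delta_stat(a, b)), 100)
  }
  expect_error(delta_stat(0, 0), "zero")
})

test_that("relative variation quantifies sensitivity to filtering", {
  expect_equal(relative_variation(matrix(10), matrix(8))$variation[1],
               200 / 11, tolerance = 1e-12)
  expect_equal(relative_variation(matrix(0), matrix(0))$variation[1], 0)
  m <- matrix(c(4, 0, 9, 2), 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  rv <- relative_variation(m, m)
  expect_true(all(rv$variation == 0))
  expect_equal(rv$fraction_zero, 1)
  # bounded when filtering only removes reads
  set.seed(23)
  orig <- matrix(rpois(60, 5), 20,
                 dimnames = list(paste0("e", 1:20), paste0("l", 1:3)))
  filt <- orig - matrix(rbinom(60, 2, 0.3), 20)
  filt[filt < 0] <- 0
  dimnames(filt) <- dimnames(orig)
  rv2 <- relative_variation(orig, filt)
  expect_true(all(rv2$variation >= 0))
  expect_true(all(rv2$variation <= 100 * orig / (orig + 1) + 1e-12))
  bad <- orig[1:10, ]
  expect_error(relative_variation(orig, bad), "index")
})
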