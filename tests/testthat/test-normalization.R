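toy_counts <- function() {
  matrix(c(10, 20, 5, 80, 0, 12, 40, 6,
           30, 25, 9, 160, 4, 10, 35, 14),
         ncol = 2,
         dimnames = list(paste0("e", 1:8), c("A", "B")))
}

test_that("TMM factors are 1 for identical and globally scaled libraries", {
  m <- cbind(A = c(10, 20, 30, 5, 80), B = c(10, 20, 30, 5, 80))
  expect_equal(as.numeric(tmm_factors(m)), c(1, 1))
  m2 <- cbind(A = c(10, 20, 30, 5, 80), B = 2 * c(10, 20, 30, 5, 80))
  expect_equal(as.numeric(tmm_factors(m2)), c(1, 1))
})

test_that("TMM factors match the literal-formula oracle and edgeR", {
  m <- toy_counts()
  f <- tmm_factors(m)
  expect_equal(as.numeric(f), as.numeric(tmm_oracle(m)),
               tolerance = 1e-12)
  skip_if_not_installed("edgeR")
  f_edger <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(as.numeric(f), as.numeric(f_edger), tolerance = 1e-8)
  # and on a larger random table
  set.seed(31)
  big <- matrix(rnbinom(400, mu = 60, size = 2), ncol = 4,
                dimnames = list(NULL, paste0("l", 1:4)))
  expect_equal(as.numeric(tmm_factors(big)),
               as.numeric(edgeR::calcNormFactors(big, method = "TMM")),
               tolerance = 1e-8)
})

test_that("TMM is insensitive to positive rescaling of one library", {
  # M and A are library-size scaled, so only the inverse-variance
  # weights feel the absolute counts: near-invariance, not identity
  m <- toy_counts()
  m2 <- m
  m2[, 2] <- m2[, 2] * 7
  expect_equal(as.numeric(tmm_factors(m)), as.numeric(tmm_factors(m2)),
               tolerance = 0.01)
  expect_error(tmm_factors(cbind(A = c(0, 0), B = c(1, 2))), "all-zero")
  expect_error(tmm_factors(matrix(1:4, ncol = 1)), "two libraries")
})

test_that("size-factor application preserves order and is a TMM fixed point", {
  set.seed(41)
  m <- matrix(rnbinom(600, mu = 80, size = 3) + 1, ncol = 3,
              dimnames = list(NULL, c("A", "B", "C")))
  m[, 2] <- m[, 2] * 2  # depth difference for the factors to absorb
  f <- tmm_factors(m)
  norm <- apply_size_factors(m, f)
  for (j in 1:3)
    expect_equal(order(norm[, j]), order(m[, j]))
  # the normalized matrix is already depth-corrected, so re-estimation
  # under equal library sizes recovers unit factors (TMM itself is
  # scale-free, so the sizes must be supplied)
  f2 <- tmm_factors(norm, lib_sizes = rep(1, ncol(norm)))
  expect_equal(as.numeric(f2), c(1, 1, 1), tolerance = 0.02)
  expect_error(apply_size_factors(m, c(X = 1, Y = 1, Z = 1)), "A")
})

test_that("RPKM follows counts over kilobases times millions mapped", {
  m <- matrix(c(1000, 999000), ncol = 1,
              dimnames = list(c("e1", "e2"), "l1"))  # N.j = 1e6
  expect_equal(rpkm(m, lengths = c(1000, 500))["e1", ], 1000)
  m2 <- matrix(c(500, 19999500), ncol = 1,
               dimnames = list(c("e1", "e2"), "l1"))  # N.j = 2e7
  expect_equal(rpkm(m2, lengths = c(2000, 100))["e1", ], 12.5)
  expect_equal(rpkm(matrix(c(0, 10), ncol = 1), lengths = c(50, 50))[1],
               0)
  expect_error(rpkm(matrix(c(0, 0), ncol = 1), lengths = c(50, 50)),
               "zero total")
})

test_that("between-lane full-quantile equalizes order statistics", {
  m <- cbind(A = c(1, 2, 3), B = c(2, 4, 6))
  out <- fq_between_lane(m)
  expect_equal(unname(out[, "A"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "B"]), c(1.5, 3, 4.5))
  # identical columns unchanged
  m2 <- cbind(A = c(5, 1, 9), B = c(5, 1, 9))
  expect_equal(fq_between_lane(m2), m2)
  # tie-free: all columns share an identical sorted vector afterwards
  set.seed(5)
  m3 <- matrix(rlnorm(300), ncol = 3)
  out3 <- fq_between_lane(m3)
  expect_equal(sort(out3[, 2]), sort(out3[, 1]))
  expect_equal(sort(out3[, 3]), sort(out3[, 1]))
  # ranks within each library and the grand mean are preserved
  for (j in 1:3)
    expect_equal(order(out3[, j]), order(m3[, j]))
  expect_equal(mean(out3), mean(m3))
})

test_that("within-lane full-quantile equalizes covariate strata", {
  # two strata where stratum 2 holds 10x the values of stratum 1
  x <- c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50)
  cov <- 1:10
  out <- fq_within_lane(matrix(x, ncol = 1), cov, n_strata = 2)
  expect_equal(median(out[1:5]), median(out[6:10]))
  expect_equal(sort(out[1:5]), sort(out[6:10]))
  # constant covariate with identical stratum compositions: unchanged
  x2 <- rep(c(2, 4, 6, 8), 2)
  out2 <- fq_within_lane(matrix(x2, ncol = 1), rep(1, 8), n_strata = 2)
  expect_equal(as.numeric(out2), x2)
  expect_error(fq_within_lane(matrix(1:4, ncol = 1), 1:4, n_strata = 9),
               "strata")
})

test_that("within-lane full-quantile removes a covariate trend", {
  set.seed(17)
  n <- 1000
  covariate <- sort(rlnorm(n, 5, 1))
  counts <- rlnorm(n, 2, 1) * (covariate / 100)  # built-in trend
  out <- fq_within_lane(cbind(counts), covariate, n_strata = 10)
  # per-stratum distributions nearly coincide (KS distance ~ 0)
  stratum <- rep(1:10, each = 100)[rank(covariate, ties.method = "first")]
  ks <- suppressWarnings(stats::ks.test(out[stratum == 1],
                                        out[stratum == 10])$statistic)
  expect_lt(unname(ks), 0.1)
  # and the rank correlation with the covariate collapses
  expect_lt(abs(cor(out[, 1], covariate, method = "spearman")), 0.1)
  expect_gt(cor(counts, covariate, method = "spearman"), 0.5)
})
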