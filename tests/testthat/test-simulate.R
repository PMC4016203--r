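test_that("positional preference is deterministic and uniform in the limit", {
  w1 <- simulate_preference(1000, k = 1, decay = 500, read_length = 50,
                            seed = 4)
  w2 <- simulate_preference(1000, k = 1, decay = 500, read_length = 50,
                            seed = 4)
  expect_identical(w1, w2)
  expect_equal(sum(w1), 1)
  expect_equal(length(w1), 951L)
  # gamma concentration: near-uniform weights at large shape
  wu <- simulate_preference(1000, k = 1e6, decay = Inf, read_length = 50,
                            seed = 4)
  expect_lt(max(wu) / min(wu), 1.05)
  expect_equal(attr(wu, "efficiency"), 1, tolerance = 0.01)
  expect_error(simulate_preference(40, 1, Inf, read_length = 50),
               "shorter than the read length")
})

test_that("sampled start positions reproduce the preference weights", {
  w <- simulate_preference(2000, k = 1, decay = Inf, read_length = 50,
                           seed = 6)
  set.seed(60)
  draws <- sample.int(length(w), 1e5, replace = TRUE, prob = w)
  emp <- tabulate(draws, length(w)) / 1e5
  expect_gt(cor(emp, as.numeric(w)), 0.9)
})

test_that("the 3' decay suppresses weights toward the transcript end", {
  w <- simulate_preference(2000, k = Inf, decay = 200, read_length = 50,
                           seed = 2)
  ns <- length(w)
  expect_lt(mean(w[(ns - 100):ns]), mean(w[1:100]) / 5)
  expect_lt(attr(w, "efficiency"), 1)
})

test_that("simulated libraries honor depth, mismatch and multiread settings", {
  cfg <- sim_config(seed = 3, n_exons = 40, depth = 2e4,
                    multiread_fraction = 0.1, lowsim_fraction = 0.05,
                    mismatch_rate = 0)
  truth <- simulate_truth(cfg, with_sequences = FALSE)
  aln <- simulate_library(truth, replicate_seed = 30)
  prim <- bitwAnd(aln$flag, 256L) == 0L
  expect_equal(sum(prim), nrow(aln) - sum(aln$flag == 256L))
  # depth within Poisson error
  expect_lt(abs(sum(prim) - 2e4) / 2e4, 0.05)
  # multiread fraction of primaries, and NH consistency
  expect_equal(mean(aln$nh[prim] == 2L), 0.1, tolerance = 0.25)
  expect_true(all(aln$nh[!prim] == 2L))
  # injected low-similarity reads fall strictly below 97%
  sim <- alignment_similarity(aln)
  expect_equal(mean(sim[prim] < 0.97), 0.05, tolerance = 0.3)
  # zero mismatch rate elsewhere: all other records at similarity 1
  expect_true(all(sim[sim >= 0.97] == 1))
  # reads land inside their exon
  gt0 <- simulate_library(truth, replicate_seed = 30, depth = 0)
  expect_equal(nrow(gt0), 0L)
})

test_that("expected totcounts track expression times length", {
  cfg <- sim_config(seed = 8, n_exons = 200, depth = 1e5,
                    preference_k = Inf, three_prime_decay = Inf,
                    expr_sdlog = 1)
  truth <- simulate_truth(cfg, with_sequences = FALSE)
  aln <- simulate_library(truth, replicate_seed = 80)
  tt <- summarize_exon_counts(aln, truth$exons)$totcounts
  ns <- truth$exons$length - cfg$read_length + 1L
  lambda <- 1e5 * truth$expression * ns / sum(truth$expression * ns)
  # chi-square goodness of fit against the Poisson expectations
  use <- lambda >= 5
  chi2 <- sum((tt[use] - lambda[use])^2 / lambda[use])
  p <- stats::pchisq(chi2, df = sum(use), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("spike-in panels are log-uniform with known concentrations", {
  cfg <- sim_config(seed = 5, read_length = 50)
  panel <- make_spikein_panel(10, conc_range = c(1e-3, 1), cfg)
  lr <- diff(log(panel$concentrations$concentration))
  expect_equal(max(lr) - min(lr), 0, tolerance = 1e-12)
  expect_equal(panel$exons$exon_id, panel$concentrations$id)
  expect_equal(Biostrings::width(panel$reference), panel$exons$length)
  # an equal-concentration pair for discrepancy experiments
  pair <- make_spikein_panel(2, conc_range = c(7e-7, 7e-7), cfg,
                             with_sequences = FALSE)
  expect_equal(pair$concentrations$concentration, rep(7e-7, 2))
})

test_that("coverage patterns are reproducible across replicate libraries", {
  cfg <- sim_config(seed = 12, n_exons = 4, depth = 4e4,
                    preference_k = 0.5, length_meanlog = log(800),
                    length_sdlog = 0.2)
  truth <- simulate_truth(cfg, with_sequences = FALSE)
  a1 <- simulate_library(truth, replicate_seed = 121)
  a2 <- simulate_library(truth, replicate_seed = 122)
  for (i in seq_len(4)) {
    p1 <- coverage_profile(truth$exons[i, ], a1)
    p2 <- coverage_profile(truth$exons[i, ], a2)
    expect_gt(cor(p1, p2), 0.8)
  }
})

test_that("identical configurations yield byte-identical fixture sets", {
  cfg <- sim_config(seed = 21, n_exons = 15, depth = 3000,
                    multiread_fraction = 0.05, n_replicates = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_experiment(cfg, d1)$files
  f2 <- simulate_experiment(cfg, d2)$files
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # conservation: one FASTQ record per primary SAM record
  sam <- readLines(f1[["rep1_sam"]])
  rec <- sam[!grepl("^@", sam)]
  flags <- as.integer(vapply(strsplit(rec, "\t"), `[[`, "", 2))
  n_primary <- sum(bitwAnd(flags, 256L) == 0L)
  n_fastq <- length(readLines(f1[["rep1_fastq"]])) / 4
  expect_equal(n_primary, n_fastq)
  # SAM round-trips through the reader
  aln <- read_alignments(f1[["rep1_sam"]])
  expect_equal(nrow(aln), length(rec))
  expect_true(all(c("nm", "nh") %in% names(aln)))
})
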