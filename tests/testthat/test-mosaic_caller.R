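test_that("compute_aaf returns exact ratios with Clopper-Pearson intervals", {
  expect_equal(compute_aaf(18, 100)$value, 0.18)
  z <- compute_aaf(0, 50)
  expect_equal(z$value, 0)
  expect_equal(z$ci_low, 0)
  mid <- compute_aaf(65, 130)
  expect_true(mid$ci_low < 0.5 && mid$ci_high > 0.5)

  # oracle: stats::binom.test implements the exact Clopper-Pearson interval
  grid <- expand.grid(x = c(0, 1, 5, 24, 65, 130), n = 130)
  grid <- grid[grid$x <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    got <- compute_aaf(grid$x[i], grid$n[i], alpha = 0.05)
    ref <- binom.test(grid$x[i], grid$n[i])$conf.int
    expect_equal(c(got$ci_low, got$ci_high), as.numeric(ref),
                 tolerance = 1e-10, label = paste(grid$x[i], grid$n[i]))
  }
  # interval ordering invariant
  est <- compute_aaf(0:30, 30)
  expect_true(all(est$ci_low <= est$value & est$value <= est$ci_high))
})

test_that("compute_aaf validates its inputs", {
  expect_error(compute_aaf(5, 0), "total_reads")
  expect_error(compute_aaf(10, 5), "exceed")
  expect_error(compute_aaf(-1, 5), ">= 0")
})

test_that("normal-approximation thresholds reproduce the closed form", {
  thr <- derive_het_thresholds(48, 0.05, "normal")
  expect_equal(thr$lower, 0.5 - qnorm(0.975) * 0.5 / sqrt(48))
  expect_equal(thr$lower, 0.35855, tolerance = 1e-4)
  expect_equal(thr$upper, 0.64145, tolerance = 1e-4)

  thr2 <- derive_het_thresholds(130, 0.001, "normal")
  expect_equal(thr2$lower, 0.3557, tolerance = 1e-4)

  # interval shrinks toward (0.5, 0.5) at large depth
  big <- derive_het_thresholds(1e6, 0.05, "normal")
  expect_equal(big$lower, 0.5, tolerance = 1e-2)
  expect_true(big$lower > derive_het_thresholds(100, 0.05, "normal")$lower)
})

test_that("exact thresholds cap the heterozygote tail probability at alpha", {
  for (d in c(20, 47, 130, 301)) {
    thr <- derive_het_thresholds(d, 0.05, "exact")
    k <- round(thr$lower * d) - 1  # largest count strictly below threshold
    expect_lte(2 * pbinom(k, d, 0.5), 0.05)
    # one step wider would exceed alpha
    expect_gt(2 * pbinom(k + 1, d, 0.5), 0.05)
    expect_equal(thr$lower + thr$upper, 1)  # symmetric about 0.5
  }
  widths <- with(derive_het_thresholds(seq(20, 400, by = 20), 0.05, "exact"),
                 upper - lower)
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("classification follows the reporting criteria", {
  pol <- threshold_policy()
  expect_identical(classify_percent(17.5, "female", "autosome")$status,
                   "candidate_mosaic_low")
  expect_identical(classify_percent(79.7, "female", "autosome")$status,
                   "candidate_mosaic_high")
  expect_identical(classify_percent(85.0, "male", "X_nonPAR")$status,
                   "candidate_mosaic_hemi")
  expect_identical(classify_observation(50, 100, "male", "autosome")$status,
                   "consistent_het")
  expect_identical(classify_observation(3, 10, "female", "autosome")$status,
                   "insufficient_depth")
  # strict inequality at the diploid boundary: exactly 36% is het-consistent
  expect_identical(classify_percent(36.0, "female", "autosome")$status,
                   "consistent_het")
  # hemizygous floor is inclusive: exactly 10% is a candidate
  expect_identical(classify_percent(10.0, "male", "X_nonPAR")$status,
                   "candidate_mosaic_hemi")
  expect_identical(classify_percent(5.0, "male", "X_nonPAR")$status,
                   "below_detection")
  expect_identical(classify_percent(95.0, "male", "X_nonPAR")$status,
                   "consistent_hemi")
  # X in a female is diploid; X with unknown sex is uncallable, not guessed
  expect_identical(classify_percent(45.0, "female", "X_nonPAR")$status,
                   "consistent_het")
  expect_identical(classify_percent(45.0, "unknown", "X_nonPAR")$status,
                   "uncallable")
})

test_that("diploid low/high classification is symmetric about 0.5", {
  set.seed(42)
  depth <- 200
  alts <- sample(0:depth, 60)
  lo <- classify_observation(alts, depth, "female", "autosome")$status
  hi <- classify_observation(depth - alts, depth, "female", "autosome")$status
  expect_identical(lo == "candidate_mosaic_low", hi == "candidate_mosaic_high")
  expect_identical(lo == "consistent_het", hi == "consistent_het")
})

test_that("fixed-mode classification is pure and deterministic", {
  a <- classify_observation(23, 130, "female", "autosome")
  b <- classify_observation(23, 130, "female", "autosome")
  expect_identical(a, b)
})

test_that("depth-adaptive mode widens thresholds at low depth", {
  pol <- threshold_policy(mode = "depth_adaptive", alpha = 0.05)
  # 9/25 = 0.36 exactly: fixed mode het-consistent; adaptive at depth 25
  # requires a much lower AAF before flagging
  expect_identical(classify_observation(8, 25, "female", "autosome",
                                        pol)$status,
                   "consistent_het")
  expect_identical(classify_observation(8, 25, "female", "autosome")$status,
                   "candidate_mosaic_low")
  # at high depth the adaptive interval is narrower than the fixed one
  thr <- derive_het_thresholds(5000, 0.05, "exact")
  expect_gt(thr$lower, 0.36)
  expect_identical(classify_observation(0.4 * 5000, 5000, "female",
                                        "autosome", pol)$status,
                   "candidate_mosaic_low")
})

test_that("aaf_concordance is a Spearman rank correlation", {
  expect_equal(aaf_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(aaf_concordance(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1)), -1)
  expect_equal(aaf_concordance(c(0.1, 0.2, 0.3, 0.4),
                               c(0.12, 0.18, 0.33, 0.41)), 1)
  expect_error(aaf_concordance(c(0.1, 0.2), c(0.1, 0.2)), "at least 3")
  expect_error(aaf_concordance(c(0.1, 0.2, 0.3), c(0.1, 0.2)), "equal length")
})

test_that("filter_common removes frequent variants and keeps unknowns", {
  rec <- data.frame(locus = c("a", "b", "c"), x = 1:3)
  af <- c(a = 0.2, b = 0.001)
  suppressMessages(out <- filter_common(rec, af, threshold = 0.01))
  expect_identical(out$kept$locus, c("b", "c"))
  expect_identical(out$removed$locus, "a")
  expect_identical(out$n_in, 3L)
  expect_identical(out$n_kept + out$n_removed, out$n_in)
  expect_message(filter_common(rec, af), "no population frequency for c")

  empty <- filter_common(rec[0, ], af)
  expect_identical(empty$n_in, 0L)
})
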