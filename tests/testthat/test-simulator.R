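# independent oracle: P(flagged) for the fixed diploid policy by direct
# summation of binomial masses, with its own inequality logic
oracle_flag_prob <- function(f, depth, error_rate = 0) {
  f2 <- f * (1 - error_rate) + (1 - f) * error_rate / 3
  ks <- 0:depth
  flagged <- (ks / depth < 0.36) | (ks / depth > 0.64)
  sum(dbinom(ks[flagged], depth, f2))
}

test_that("sample_read_counts matches binomial moments and boundaries", {
  set.seed(1)
  expect_equal(sample_read_counts(0, 1000, 0)$alt_reads, 0)
  expect_equal(sample_read_counts(1, 50, 0)$alt_reads, 50)
  reps <- sample_read_counts(rep(0.5, 1e4), 130, 0)
  se <- sqrt(0.25 / 130 / 1e4)
  expect_lt(abs(mean(reps$alt_reads / reps$total_reads) - 0.5), 3 * se)
  # error model pushes a zero-fraction site to e/3 expected alt fraction
  err <- sample_read_counts(rep(0, 1e4), 100, 0.03)
  expect_equal(mean(err$alt_reads / 100), 0.01, tolerance = 0.15)
})

test_that("sample_depths respects the configured floor", {
  set.seed(2)
  cfg <- simulation_config(depth_mean = 130, depth_min = 20)
  d <- sample_depths(5000, cfg)
  expect_true(all(d >= 20))
  expect_equal(mean(d), 130, tolerance = 0.05)
})

test_that("Monte-Carlo operating characteristics match the exact oracle", {
  cfg <- simulation_config(true_fractions = c(0.5, 0.3), error_rate = 0,
                           seed = 5)
  oc <- operating_characteristics(cfg, depths = c(40, 130), n_reps = 4000)
  expect_s3_class(oc, "operating_characteristics")
  expect_equal(nrow(oc), 4L)
  for (i in seq_len(nrow(oc))) {
    p_exact <- oracle_flag_prob(oc$true_fraction[i], oc$depth[i])
    se <- sqrt(max(p_exact * (1 - p_exact), 1e-9) / oc$n_reps[i])
    expect_lt(abs(oc$p_flagged_mosaic[i] - p_exact), 4 * se + 1e-12,
              label = sprintf("f=%.2f depth=%d", oc$true_fraction[i],
                              oc$depth[i]))
  }
  expect_true(all(oc$mc_stderr ==
                    sqrt(oc$p_flagged_mosaic * (1 - oc$p_flagged_mosaic) /
                           oc$n_reps)))
  # reproducible for a fixed seed
  oc2 <- operating_characteristics(cfg, depths = c(40, 130), n_reps = 4000)
  expect_identical(oc, oc2)
})

test_that("exact_flag_probability agrees with the independent oracle", {
  expect_equal(exact_flag_probability(0.5, 130), oracle_flag_prob(0.5, 130))
  expect_equal(exact_flag_probability(0.3, 40), oracle_flag_prob(0.3, 40))
  expect_equal(exact_flag_probability(0.18, 130, error_rate = 0.001),
               oracle_flag_prob(0.18, 130, error_rate = 0.001))
  # hemizygous context uses the 10%-90% window
  p_hemi <- exact_flag_probability(1, 60, context = "hemizygous")
  ks <- 0:60
  expect_equal(p_hemi,
               sum(dbinom(ks[ks / 60 >= 0.10 & ks / 60 <= 0.90], 60, 1)))
})

test_that("heterozygote AAF distribution is centred and dropout shifts it", {
  cfg <- simulation_config(n_variants = 2e4, seed = 9, error_rate = 0)
  h <- het_aaf_distribution(cfg)
  expect_s3_class(h, "aaf_histogram")
  mode_bin <- h$histogram$mids[which.max(h$histogram$counts)]
  expect_equal(mode_bin, 0.5, tolerance = 0.021)
  expect_equal(mean(h$aaf), 0.5, tolerance = 0.005)

  hd <- het_aaf_distribution(cfg, dropout = 0.2)
  # thinned-binomial expectation f(1-b)/(1-fb) = 0.4/0.9
  expect_equal(mean(hd$aaf), 0.4 / 0.9, tolerance = 0.005)
  expect_lt(mean(hd$aaf), mean(h$aaf))

  empty <- het_aaf_distribution(simulation_config(n_variants = 0))
  expect_identical(sum(empty$histogram$counts), 0L)
  expect_length(empty$aaf, 0)
})

test_that("type-I error of the fixed policy is non-increasing in depth", {
  depths <- c(20, 40, 80, 130, 260)
  p <- vapply(depths, function(d) exact_flag_probability(0.5, d), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("generate_trio_cohort writes a parsable cohort with planted truth", {
  cfg <- simulation_config(seed = 21, depth_min = 60, n_variants = 40)
  planted <- plant_trio_scenarios(40, cfg)
  expect_equal(nrow(planted), 40)
  expect_true(all(planted$expected_origin[planted$scenario == "de_novo"] ==
                    "de_novo"))
  dir <- file.path(tempdir(), "simcohort")
  paths <- generate_trio_cohort(planted, cfg, dir = dir)
  expect_true(all(file.exists(paths$vcf, paths$ped, paths$truth)))

  obs <- read_vcf_observations(paths$vcf, paths$ped)
  expect_equal(nrow(obs), 3 * 40)  # one observation per sample per site
  expect_setequal(unique(obs$role), c("proband", "mother", "father"))
  expect_true(all(obs$total_reads >= 60))

  # planted carriers show alternate support, clean samples near zero
  truth <- read.delim(paths$truth)
  pro <- obs[obs$role == "proband", ]
  pro <- pro[order(pro$pos), ]
  truth <- truth[order(truth$pos), ]
  planted_aaf <- pro$alt_reads / pro$total_reads
  expect_gt(min(planted_aaf[truth$f_proband >= 0.1]), 0.02)

  # determinism under a fixed seed
  paths2 <- generate_trio_cohort(planted, cfg, dir = file.path(dir, "b"))
  expect_identical(readLines(paths$vcf), readLines(paths2$vcf))

  # locus collisions are rejected
  dup <- rbind(planted, planted[1, ])
  expect_error(generate_trio_cohort(dup, cfg, dir = dir), "locus collision")

  # zero planted variants still yields a valid (empty) cohort
  p0 <- generate_trio_cohort(planted[0, ], cfg, dir = file.path(dir, "z"))
  expect_equal(nrow(read_vcf_observations(p0$vcf, p0$ped)), 0L)
})
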