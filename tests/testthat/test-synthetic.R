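test_that("simulate_genome is seed-deterministic and density-targeted", {
  g1 <- simulate_genome(2e5, target_label_density = 11, seed = 5)
  g2 <- simulate_genome(2e5, target_label_density = 11, seed = 5)
  expect_identical(g1$record$sequence, g2$record$sequence)
  g3 <- simulate_genome(2e5, target_label_density = 11, seed = 6)
  expect_false(identical(g1$record$sequence, g3$record$sequence))

  g <- simulate_genome(1e6, target_label_density = 11, seed = 7)
  # realized site count within the Poisson 99% interval around 110
  n_lab <- g$label_density * 10
  expect_true(n_lab >= qpois(0.005, 110) && n_lab <= qpois(0.995, 110))
})

test_that("with target 0 only background motif occurrences remain", {
  g <- simulate_genome(1e6, gc = 0.4, target_label_density = 0, seed = 8)
  # closed-form background expectation, both strands
  p_hit <- 2 * (0.2^4 * 0.3^3)
  expected <- (1e6 - 6) * p_hit
  n_nicks <- g$nick_density * 10
  expect_true(abs(n_nicks - expected) < 4 * sqrt(expected))
})

test_that("interval sampling honours truncation, bounds and stopping", {
  lm <- molecule_length_model()
  iv <- sample_molecule_intervals(1e6, 10, lm, seed = 3)
  lens <- iv$end - iv$start
  expect_true(all(lens >= 1e5))
  expect_true(all(iv$start >= 0) && all(iv$end <= 1e6))
  total <- sum(lens)
  expect_true(total >= 10 * 1e6 && total <= 10 * 1e6 + max(lens))
  expect_error(sample_molecule_intervals(5e4, 10, lm), "shorter")
})

test_that("length law calibration reproduces the target N50", {
  lm <- molecule_length_model(min_len = 1e5, target_n50 = 176e3,
                              target_median = 150e3)
  iv <- sample_molecule_intervals(2e7, 25, lm, seed = 9)  # > 2,000 molecules
  lens <- iv$end - iv$start
  expect_gt(nrow(iv), 2000)
  expect_lt(abs(n50(lens) - 176e3) / 176e3, 0.10)
})

test_that("corrupt_molecule is the identity under a zero noise model", {
  labs <- seq(5000, 145000, by = 10000)
  cm <- corrupt_molecule(labs, 150000, noise_model_none(), seed = 1)
  expect_equal(cm$molecule$labels, labs)
  expect_equal(cm$molecule$length, 150000)
  expect_equal(cm$truth$n_fp, 0)
  expect_equal(cm$truth$n_kept, length(labs))
})

test_that("degenerate noise settings behave as specified", {
  labs <- seq(5000, 145000, by = 10000)
  all_missed <- corrupt_molecule(labs, 150000,
                                 noise_model(fp_rate = 0, fn_prob = 1),
                                 seed = 2)
  expect_length(all_missed$molecule$labels, 0)
})

test_that("label loss matches the binomial model over many labels", {
  set.seed(10)
  n_true <- 0; n_kept <- 0
  for (k in 1:170) {
    labs <- sort(runif(100, 0, 2e5))
    labs <- labs[c(TRUE, diff(labs) > 600)]
    cm <- corrupt_molecule(labs, 2e5, noise_model(fp_rate = 0, fn_prob = 0.15,
                                                  sizing_sd_scale = 0,
                                                  stretch_mean = 1,
                                                  stretch_sd = 0, bpp = 0))
    n_true <- n_true + cm$truth$n_true
    n_kept <- n_kept + cm$truth$n_kept
  }
  expect_gt(n_true, 10000)
  drop_frac <- 1 - n_kept / n_true
  ci <- qbinom(c(0.005, 0.995), n_true, 0.15) / n_true
  expect_true(drop_frac >= ci[1] && drop_frac <= ci[2])
})

test_that("zero-noise datasets reproduce the digest on each interval", {
  g <- simulate_genome(6e5, target_label_density = 11, seed = 12)
  ds <- generate_dataset(g$record, depth = 5, noise = noise_model_none(),
                         seed = 13)
  dig <- ds$digest
  for (k in seq_len(min(25, nrow(ds$truth)))) {
    tr <- ds$truth[k, ]
    expected <- dig$labels[dig$labels >= tr$start & dig$labels < tr$end] - tr$start
    if (tr$strand == "-") expected <- rev((tr$end - tr$start) - expected)
    expect_equal(ds$bnx$molecules[[k]]$labels, expected)
  }
})

test_that("identical seeds give byte-identical BNX files", {
  g <- simulate_genome(5e5, target_label_density = 11, seed = 20)
  d1 <- generate_dataset(g$record, depth = 4, seed = 21)
  d2 <- generate_dataset(g$record, depth = 4, seed = 21)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_bnx(d1$bnx, p1); write_bnx(d2$bnx, p2)
  expect_identical(readLines(p1), readLines(p2))
  d3 <- generate_dataset(g$record, depth = 4, seed = 22)
  expect_false(identical(d1$truth$start, d3$truth$start))
})

test_that("validate_rates recovers the planted FP and FN rates", {
  g <- simulate_genome(2e6, target_label_density = 11, seed = 30)
  ds0 <- generate_dataset(g$record, depth = 3, noise = noise_model_none(),
                          seed = 31)
  vr0 <- validate_rates(ds0$bnx, ds0$truth)
  expect_equal(vr0$fp_hat, 0)
  expect_equal(vr0$fn_hat, 0)

  ds5 <- generate_dataset(g$record, depth = 15,
                          noise = noise_model(fn_prob = 0.5), seed = 32)
  vr5 <- validate_rates(ds5$bnx, ds5$truth)
  n_true <- sum(ds5$truth$n_true)
  ci <- qbinom(c(0.005, 0.995), n_true, 0.5) / n_true
  expect_true(vr5$fn_hat >= ci[1] && vr5$fn_hat <= ci[2])
})

test_that("observed molecule label gaps respect the optical resolution", {
  g <- simulate_genome(5e5, target_label_density = 11, seed = 40)
  ds <- generate_dataset(g$record, depth = 5, seed = 41)
  for (m in ds$bnx$molecules) {
    if (length(m$labels) > 1) expect_true(all(diff(m$labels) >= 500))
  }
})
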