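# Accuracy metrics: R^2, maximally differentiating frames, improvement
# slopes, adjusted R^2, cycle averages, F1/F2, paired-cone scoring and the
# bootstrap comparison.

test_that("r_squared matches its formula and unit cases", {
  obs <- c(1, 2, 3, 5, 2)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(rep(mean(obs), 5), obs), 0)
  expect_error(r_squared(1:3, rep(2, 3)), "variance")
  set.seed(21)
  for (i in 1:5) {
    pred <- stats::runif(40); o <- stats::rpois(40, 2)
    expect_equal(r_squared(pred, o), oracle_r2(pred, o), tolerance = 1e-12)
  }
})

test_that("max-diff frame selection is top-k, tie-broken, observation-blind", {
  pa <- sqrt(0:9); pb <- rep(0, 10)  # squared diffs 0..9
  expect_equal(select_max_diff_frames(pa, pb), c(9L, 10L))
  # identical predictions: deterministic tie-broken set (lowest indices)
  expect_equal(select_max_diff_frames(rep(1, 10), rep(1, 10)), 1:2)
  set.seed(22)
  for (i in 1:5) {
    a <- stats::rnorm(50); b <- stats::rnorm(50)
    expect_equal(select_max_diff_frames(a, b), oracle_maxdiff(a, b))
  }
})

test_that("improvement slope is least squares through the origin with exclusions", {
  a <- c(0.2, 0.4, 0.6)
  expect_equal(improvement_slope(1.2 * a, a), 1.2, tolerance = 1e-12)
  expect_equal(improvement_slope(0.6, 0.5), 1.2, tolerance = 1e-12)
  set.seed(23)
  for (i in 1:5) {
    a <- stats::runif(20); b <- 1.3 * a + stats::rnorm(20, 0, 0.05)
    expect_equal(improvement_slope(b, a), oracle_slope(b, a),
                 tolerance = 1e-12)
  }
  # negative-reference cells are excluded only when asked
  a2 <- c(-0.5, 0.5); b2 <- c(0.4, 0.6)
  expect_equal(improvement_slope(b2, a2, exclude_negative_reference = TRUE),
               1.2, tolerance = 1e-12)
})

test_that("adjusted R^2 is gain/offset invariant and matches the two-loop oracle", {
  tpl <- sin(seq(0, 4 * pi, length.out = 60)) + 2
  trials <- matrix(rep(tpl, 5), 5, byrow = TRUE)
  expect_equal(adjusted_r_squared(trials, tpl), 1, tolerance = 1e-12)
  expect_equal(adjusted_r_squared(trials, 3 * tpl + 7), 1, tolerance = 1e-12)
  set.seed(24)
  z <- stats::runif(80, 0.5, 4)
  trials <- matrix(stats::rpois(12 * 80, rep(z, each = 12)), 12)
  expect_equal(adjusted_r_squared(trials, z), oracle_adjusted_r2(trials, z),
               tolerance = 1e-12)
})

test_that("adjusted R^2 approaches 1 with more repeats of the true rate", {
  set.seed(25)
  z <- stats::runif(100, 0.5, 4)
  vals <- vapply(c(5, 20, 80), function(R) {
    trials <- matrix(stats::rpois(R * 100, rep(z, each = R)), R)
    adjusted_r_squared(trials, z)
  }, 0)
  expect_gt(vals[3], 0.95)
  expect_lt(abs(vals[3] - 1), abs(vals[1] - 1) + 0.05)
})

test_that("cycle averages fold correctly and conserve spikes", {
  # constant rate folds flat
  flat <- cycle_average(rep(2, 60), frame_rate_hz = 12, temporal_freq_hz = 2)
  expect_equal(flat, rep(2, 6))
  # sinusoidal profile is recovered
  prof <- 2 + sin(2 * pi * (0:5) / 6)
  counts <- rep(prof, 10)
  expect_equal(cycle_average(counts, 12, 2), prof, tolerance = 1e-12)
  # conservation: total spikes equal between raw and folded representations
  set.seed(26)
  cts <- stats::rpois(120, 1.5)
  ca <- cycle_average(cts, 12, 2)
  expect_equal(sum(ca) * 20, sum(cts), tolerance = 1e-10)
  expect_error(cycle_average(1:10, 12, 2), "whole number")
})

test_that("F1/F2 amplitudes detect frequency doubling", {
  tt <- (0:23) / 24
  pure <- sin(2 * pi * tt)
  amps <- f1_f2_amplitudes(pure)
  expect_equal(amps[["F1"]], 1, tolerance = 1e-10)
  expect_lt(amps[["F2"]], 1e-10)
  rect <- abs(sin(2 * pi * tt))  # full-wave rectified: doubled frequency
  amps2 <- f1_f2_amplitudes(rect)
  expect_lt(amps2[["F1"]], 1e-10)
  expect_gt(amps2[["F2"]], 0.2)
  # random profile against a direct DFT oracle
  set.seed(27)
  x <- stats::rnorm(12)
  direct <- vapply(1:2, function(k)
    2 * Mod(sum(x * exp(-2i * pi * k * (0:11) / 12))) / 12, 0)
  expect_equal(unname(f1_f2_amplitudes(x)), direct, tolerance = 1e-10)
})

test_that("paired response tables normalize by the maximum", {
  expect_equal(paired_response_table(c(10, 5, 2, 8)), c(1, 0.5, 0.2, 0.8))
  expect_equal(paired_response_table(c(3, 3, 3, 3)), rep(1, 4))
  m <- rbind(c(10, 5, 2, 8), c(4, 2, 1, 4))
  n <- paired_response_table(m)
  expect_equal(unname(apply(n, 1, max)), c(1, 1))
  expect_equal(n[1, ], c(1, 0.5, 0.2, 0.8))
  expect_equal(paired_prediction_score(c(1, 0.5, 0.2), c(1, 0.5, 0.2)), 1)
  set.seed(28)
  a <- stats::runif(200); b <- stats::runif(200)
  expect_lt(paired_prediction_score(a, b), 0.05)
  expect_equal(paired_prediction_score(a, b), stats::cor(a, b)^2,
               tolerance = 1e-12)
})

test_that("bootstrap model comparison flags dominating models only", {
  set.seed(29)
  measured <- stats::runif(30)
  good <- measured + stats::rnorm(30, 0, 0.01)
  bad <- stats::runif(30)
  res <- bootstrap_model_comparison(measured,
                                    list(good = good, bad = bad),
                                    n_boot = 500, seed = 1)
  expect_true(res$significant[["bad"]])
  res2 <- bootstrap_model_comparison(measured,
                                     list(a = good, b = good),
                                     n_boot = 500, seed = 1)
  expect_false(res2$significant[["b"]])
  # deterministic per seed
  res3 <- bootstrap_model_comparison(measured,
                                     list(good = good, bad = bad),
                                     n_boot = 500, seed = 1)
  expect_identical(res$fifth_percentile, res3$fifth_percentile)
})

test_that("bootstrap percentile agrees with exhaustive resampling on a tiny case",
{
  # n = 10 pairs but only distinct values in a pattern we can enumerate is
  # infeasible; instead compare a large bootstrap against a second
  # independent large bootstrap: the 5th percentiles must agree closely
  set.seed(30)
  measured <- stats::runif(12)
  p1 <- measured + stats::rnorm(12, 0, 0.08)
  p2 <- measured + stats::rnorm(12, 0, 0.4)
  r1 <- bootstrap_model_comparison(measured, list(a = p1, b = p2),
                                   n_boot = 4000, seed = 5)
  r2 <- bootstrap_model_comparison(measured, list(a = p1, b = p2),
                                   n_boot = 4000, seed = 99)
  expect_lt(abs(r1$fifth_percentile - r2$fifth_percentile), 0.1)
})

test_that("cancellation index dichotomizes at one half", {
  ci <- cancellation_index(10, 9)
  expect_equal(ci$ratio, 0.9)
  expect_true(ci$non_cancelling)
  ci2 <- cancellation_index(10, 1)
  expect_equal(ci2$ratio, 0.1)
  expect_false(ci2$non_cancelling)
  expect_error(cancellation_index(0, 1), "positive")
})

test_that("null phase zeros the summed linear drive", {
  set.seed(31)
  mosaic <- make_mosaic(5, seed = 32)
  w <- stats::rnorm(5)
  period <- 25
  ph <- null_phase(w, mosaic, period)
  drive <- function(phi) sum(w * grating_attenuation(mosaic$sigma, period) *
                               sin(2 * pi * mosaic$x / period + phi))
  expect_lt(abs(drive(ph)), 1e-10)
})
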