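# Estimation: train/test splitting, the coordinate sub-steps, the greedy
# assignment search and the model reductions.

test_that("train/test split is exact, disjoint, exhaustive and blocked", {
  sp <- split_train_test(100, frame_rate_hz = 12, train_fraction = 0.8,
                         seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  # test frames form contiguous blocks
  expect_true(all(diff(sp$test) >= 1))
  expect_error(split_train_test(5), "at least 10")
  # blocks land throughout the recording across seeds
  Tn <- 12 * 60 * 10  # ten minutes
  hits <- numeric(Tn)
  for (s in 1:40) {
    sp <- split_train_test(Tn, 12, 0.8, block_seconds = 60, seed = s)
    expect_length(sp$test, round(0.2 * Tn))
    hits[sp$test] <- hits[sp$test] + 1
  }
  # every fifth of the recording receives test blocks under some seed
  fifths <- split(hits, rep(1:5, each = Tn / 5))
  expect_true(all(vapply(fifths, sum, 0) > 0))
  # deterministic per seed
  expect_identical(split_train_test(500, seed = 3),
                   split_train_test(500, seed = 3))
})

test_that("weight step agrees with an independent generic ML optimizer", {
  set.seed(61)
  C <- 3; Tn <- 3000
  X <- matrix(stats::rnorm(C * Tn), C, Tn)
  w_true <- c(1.2, -0.8, 0.5)
  gx <- seq(-6, 6, length.out = 8)
  g <- nl_spline(gx, log1p(exp(gx)))
  z <- pmax(eval_spline(g, drop(crossprod(X, w_true))), 1e-6)
  counts <- stats::rpois(Tn, z)
  sw <- rgcsubunits:::step_w(X, rep(0.1, C), g, counts, 1e-6, maxit = 200)
  # independent oracle: plain Nelder-Mead on an independently coded negLL
  # (same spline output nonlinearity, evaluated directly via splinefun)
  gfn <- stats::splinefun(gx, log1p(exp(gx)), method = "natural")
  negll <- function(w) {
    zz <- pmax(gfn(colSums(w * X)), 1e-6)
    -(sum(counts * log(zz)) - sum(zz))
  }
  ref <- stats::optim(rep(0.1, C), negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(sw$w, ref$par, tolerance = 1e-2)
  expect_gte(-ref$value, sw$ll - 1e-2)
  expect_lte(-ref$value, sw$ll + 1e-2)
})

test_that("continuous fit recovers within-subunit cone weights", {
  # one 2-cone subunit with weights (0.7, 0.3), 16 minutes of frames
  truth <- subunit_model(matrix(1, 1, 2), matrix(c(0.7, 0.3), 1),
                         subunit_weights = -1.5,
                         f = init_f(),
                         g = nl_spline(seq(-0.5, 2, length.out = 8),
                                       2 * log1p(exp(3 * (seq(-0.5, 2,
                                         length.out = 8) - 0.6)))))
  stim <- sta_temporal_align(white_noise_cone_stimulus(2, 16, seed = 62))
  counts <- simulate_spikes(truth, stim, seed = 63)
  m0 <- rgcsubunits:::init_model_at(matrix(1, 1, 2), stim)
  fit <- fit_continuous(m0, stim, counts, fit_config(seed = 64))
  expect_lt(max(abs(fit$model$cone_weights - truth$cone_weights)), 0.05)
  # training log-likelihood never decreases along the trace
  ll <- fit$trace$logLik
  expect_true(all(diff(ll) >= -1e-9 * (abs(ll[-1]) + 1)))
})

test_that("zero-variance stimulus leaves cone weights at initialization with a flag", {
  stim <- cone_stimulus(matrix(0.5, 3, 200))
  counts <- rep(1L, 200)
  m0 <- subunit_model(rbind(c(1, 1, 0), c(0, 0, 1)))
  fit <- fit_continuous(m0, stim, counts, fit_config(), rounds = 2)
  expect_equal(fit$model$cone_weights, m0$cone_weights)
  expect_true(any(grepl("zero-variance", fit$flags)))
})

test_that("greedy search recovers a planted 2-cone subunit across seeds", {
  truth <- example_ground_truth(5, c(2, 1, 1, 1))
  hits <- 0
  for (s in 1:5) {
    stim <- sta_temporal_align(white_noise_cone_stimulus(5, 16,
                                                         seed = 70 + s))
    counts <- simulate_spikes(truth, stim, seed = 80 + s)
    fit <- fit_subunit_model(stim, counts, fit_config(seed = 90 + s))
    expect_lte(nrow(fit$merge_history), 4)  # at most C - 1 rounds
    expect_true(all(colSums(fit$model$indicator) == 1))
    if (same_partition(fit$model$indicator, truth$indicator)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("greedy fits are deterministic given data and seed", {
  truth <- example_ground_truth(4, c(2, 1, 1))
  stim <- sta_temporal_align(white_noise_cone_stimulus(4, 4, seed = 101))
  counts <- simulate_spikes(truth, stim, seed = 102)
  f1 <- fit_subunit_model(stim, counts, fit_config(seed = 103))
  f2 <- fit_subunit_model(stim, counts, fit_config(seed = 103))
  expect_identical(f1$model, f2$model)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$merge_history, f2$merge_history)
})

test_that("LN data yield few or no merges", {
  # single-cone subunits with a linear f: the truth is an LN model
  C <- 5
  lin <- nl_spline(seq(-3, 3, length.out = 8), seq(-3, 3, length.out = 8))
  truth <- subunit_model(diag(C), subunit_weights = -c(1, 0.8, 1.2, 0.9, 1.1),
                         f = lin,
                         g = nl_spline(seq(-2, 6, length.out = 8),
                                       0.7 * log1p(exp(seq(-2, 6,
                                         length.out = 8) - 1))))
  stim <- sta_temporal_align(white_noise_cone_stimulus(C, 8, seed = 111))
  counts <- simulate_spikes(truth, stim, seed = 112)
  fit <- fit_subunit_model(stim, counts, fit_config(seed = 113))
  expect_gte(nrow(fit$model$indicator), C - 2)
})

test_that("LN fit recovers weights and the single-cone fit matches it on linear data", {
  C <- 4
  w_true <- c(-1, -0.7, -1.3, -0.9)
  g_true <- nl_spline(seq(-2, 6, length.out = 8),
                      0.8 * log1p(exp(seq(-2, 6, length.out = 8) - 1)))
  truth <- ln_model(w_true, g_true)
  stim <- sta_temporal_align(white_noise_cone_stimulus(C, 12, seed = 121))
  counts <- simulate_spikes(truth, stim, seed = 122)
  lnfit <- fit_ln_model(stim, counts, fit_config(seed = 123))
  # weights recovered up to a common positive scale (absorbed by g)
  scale <- sum(coef(lnfit) * w_true) / sum(coef(lnfit)^2)
  expect_gt(scale, 0)
  rel_rms <- sqrt(mean((scale * coef(lnfit) - w_true)^2)) /
    sqrt(mean(w_true^2))
  expect_lt(rel_rms, 0.05)
  # rate predictions match the truth closely on held-out frames
  test_stim <- rgcsubunits:::stim_subset(stim, lnfit$test)
  expect_lt(mean(abs(predict(lnfit, test_stim) - predict(truth, test_stim))),
            0.05)
  scfit <- fit_single_cone_model(stim, counts, fit_config(seed = 123))
  expect_lt(mean(abs(predict(scfit, test_stim) - predict(lnfit, test_stim))),
            0.05)
})

test_that("a one-cone cell reduces to a 1-D rate curve fit", {
  g_true <- nl_spline(seq(-1.5, 1.5, length.out = 8),
                      log1p(exp(2 * seq(-1.5, 1.5, length.out = 8))))
  truth <- ln_model(-1, g_true)
  stim <- sta_temporal_align(white_noise_cone_stimulus(1, 6, seed = 131))
  counts <- simulate_spikes(truth, stim, seed = 132)
  fit <- fit_single_cone_model(stim, counts, fit_config(seed = 133))
  test_stim <- rgcsubunits:::stim_subset(stim, fit$test)
  expect_gt(stats::cor(predict(fit, test_stim), predict(truth, test_stim)),
            0.98)
})

test_that("fit object methods are coherent", {
  truth <- example_ground_truth(4, c(2, 1, 1))
  stim <- sta_temporal_align(white_noise_cone_stimulus(4, 3, seed = 141))
  counts <- simulate_spikes(truth, stim, seed = 142)
  fit <- fit_subunit_model(stim, counts, fit_config(seed = 143))
  expect_s3_class(fit, "subunit_fit")
  expect_output(print(fit), "subunits")
  sm <- summary(fit)
  expect_true(is.finite(sm$r_squared_test))
  expect_lte(sm$r_squared_test, 1)
  co <- coef(fit)
  expect_equal(dim(co$assignment), dim(co$cone_weights))
  expect_equal(length(predict(fit)), n_frames(stim))
  expect_equal(length(residuals(fit)), n_frames(stim))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$logLik)
  expect_equal(attr(ll, "nobs"), length(fit$train))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3, n_frames(stim)))
  lnfit <- fit_ln_model(stim, counts, fit_config(seed = 143))
  rep <- metric_report(list(subunit = fit, ln = lnfit))
  expect_equal(rep$model, c("subunit", "ln"))
  expect_true(all(rep$r2_test <= 1))
  expect_equal(rep$r2_test[1], summary(fit)$r_squared_test)
  expect_type(rep$excluded_maxdiff, "logical")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
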