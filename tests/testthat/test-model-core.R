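# Domain types and forward model: subunit drives, firing rates, Poisson
# likelihood, LN reduction, merging and subunit-size summaries.

identity_spline <- function(range = c(-4, 4))
  nl_spline(seq(range[1], range[2], length.out = 8),
            seq(range[1], range[2], length.out = 8))

test_that("type constructors validate their invariants", {
  expect_error(cone_stimulus(matrix(c(1, Inf), 1, 2)), "finite")
  expect_error(cone_stimulus(matrix(1, 1, 1), frame_rate_hz = 0), "positive")
  expect_error(spike_counts(c(1, -1)), "non-negative")
  expect_error(spike_counts(c(1.5, 2)), "integer")
  expect_error(spike_counts(1:5, n_frames = 4), "match")
  expect_error(subunit_assignment(matrix(c(1, 1, 0, 0), 2, 2)), "exactly one")
  expect_error(subunit_assignment(matrix(c(1, 0, 1, 0), 2, 2)), "at least one")
  ind <- rbind(c(1, 1, 0), c(0, 0, 1))
  expect_error(cone_weight_matrix(rbind(c(0.5, 0.4, 0), c(0, 0, 1)), ind),
               "sum to 1")
  expect_error(cone_weight_matrix(rbind(c(0.5, 0.5, 0.1), c(0, 0, 1)), ind),
               "support|sum to 1")
})

test_that("subunit drive computes f of the pooled cone inputs", {
  # single cone, single subunit, identity f
  m <- subunit_model(matrix(1, 1, 1), f = identity_spline())
  y <- subunit_drive(m, cone_stimulus(matrix(0.5, 1, 1)))
  expect_equal(drop(y), 0.5, tolerance = 1e-12)
  # two cones pooled equally cancel within a subunit (rectifier with a
  # node at zero, so f(0) is exactly 0)
  rect_x <- c(-2, -1.5, -1, -0.5, 0, 0.5, 1.2, 2)
  m2 <- subunit_model(matrix(1, 1, 2), matrix(0.5, 1, 2),
                      f = nl_spline(rect_x, pmin(rect_x, 0)))
  y2 <- subunit_drive(m2, cone_stimulus(matrix(c(1, -1), 2, 1)))
  expect_equal(drop(y2), 0, tolerance = 1e-12)
  expect_error(subunit_drive(m2, cone_stimulus(matrix(1, 3, 2))), "cones")
})

test_that("firing rate floors at zero and matches simple hand computation", {
  # identity f and g, single-cone subunits, w = (1, -1): rate = max(x1 - x2, 0)
  m <- subunit_model(diag(2), subunit_weights = c(1, -1),
                     f = identity_spline(), g = identity_spline(c(-8, 8)))
  z <- firing_rate(m, cone_stimulus(matrix(c(2, 3), 2, 1)), rate_floor = 0)
  expect_equal(drop(z), 0)
  z2 <- firing_rate(m, cone_stimulus(matrix(c(3, 2), 2, 1)))
  expect_equal(drop(z2), 1, tolerance = 1e-12)
})

test_that("forward pass matches the scalar-loop oracle on random models", {
  for (seed in 1:6) {
    C <- sample(2:6, 1)
    S <- sample(seq_len(C), 1)
    m <- random_model(C, S, seed)
    X <- matrix(stats::rnorm(C * 50), C, 50)
    orc <- oracle_forward(m, X)
    expect_equal(subunit_drive(m, cone_stimulus(X)), orc$y,
                 tolerance = 1e-10)
    expect_equal(firing_rate(m, cone_stimulus(X)), orc$z, tolerance = 1e-10)
  }
})

test_that("Poisson log-likelihood matches direct summation and examples", {
  expect_equal(poisson_log_likelihood(rep(1, 10), rep(0L, 10)), -10)
  expect_equal(poisson_log_likelihood(rep(1, 5), rep(1L, 5)), -5)
  expect_error(poisson_log_likelihood(c(1, 0), c(0L, 0L)), "positive")
  set.seed(11)
  for (i in 1:5) {
    z <- stats::runif(30, 0.1, 4)
    r <- stats::rpois(30, z)
    expect_equal(poisson_log_likelihood(z, r), oracle_loglik(z, r),
                 tolerance = 1e-10)
  }
})

test_that("subunit model with identity structure and linear f equals the LN model", {
  set.seed(12)
  C <- 5
  w <- stats::rnorm(C)
  g <- nl_spline(seq(-4, 4, length.out = 8),
                 log1p(exp(seq(-4, 4, length.out = 8))))
  sub <- subunit_model(diag(C), diag(C), w, f = identity_spline(), g = g)
  ln <- ln_model(w, g)
  X <- matrix(stats::rnorm(C * 1000), C, 1000)
  stim <- cone_stimulus(X)
  expect_equal(firing_rate(sub, stim), ln_predict(ln, stim),
               tolerance = 1e-10)
})

test_that("row normalization convention is a pure reparameterization for linear f", {
  # pooling with unnormalized weights a and identity f equals the model
  # with A = a / sum(a) and f scaled by sum(a)
  set.seed(13)
  a <- c(0.9, 0.4, 0.2)
  m <- sum(a)
  nodes <- seq(-4, 4, length.out = 8)
  f_scaled <- nl_spline(nodes, m * nodes)  # f(v) = sum(a) * v
  g <- nl_spline(nodes, log1p(exp(nodes)))
  model <- subunit_model(matrix(1, 1, 3), matrix(a / m, 1, 3),
                         subunit_weights = -1, f = f_scaled, g = g)
  X <- matrix(stats::rnorm(3 * 200), 3, 200)
  raw <- pmax(eval_spline(g, -drop(a %*% X)), 1e-6)
  expect_equal(firing_rate(model, cone_stimulus(X)), raw, tolerance = 1e-10)
})

test_that("merging subunits preserves the partition and cone membership", {
  ind <- merge_subunits(diag(3), 1, 2)
  expect_equal(ind, rbind(c(1, 1, 0), c(0, 0, 1)))
  # successive merges from the identity end in one row of ones
  C <- 6
  ind <- diag(C)
  n_merges <- 0
  while (nrow(ind) > 1) {
    ind <- merge_subunits(ind, 1, 2)
    n_merges <- n_merges + 1
  }
  expect_equal(n_merges, C - 1)
  expect_equal(ind, matrix(1, 1, C))
  expect_error(merge_subunits(diag(3), 2, 2), "distinct")
  expect_error(merge_subunits(diag(3), 1, 4), "valid")
})

test_that("merges agree with the set-union oracle and keep column sums at 1", {
  set.seed(14)
  for (rep in 1:8) {
    C <- sample(4:8, 1)
    S <- sample(2:C, 1)
    m <- random_model(C, S, seed = 100 + rep)
    ind <- m$indicator
    sets <- apply(ind, 1, function(r) which(r == 1), simplify = FALSE)
    while (nrow(ind) > 1) {
      s1 <- sample(nrow(ind) - 1, 1); s2 <- nrow(ind)
      lo <- min(s1, s2); hi <- max(s1, s2)
      # set-union oracle mirroring the row layout: union replaces row lo,
      # row hi disappears
      sets[[lo]] <- sort(union(sets[[lo]], sets[[hi]]))
      sets[[hi]] <- NULL
      ind <- merge_subunits(ind, s1, s2)
      expect_true(all(colSums(ind) == 1))
      got <- apply(ind, 1, function(r) which(r == 1), simplify = FALSE)
      expect_setequal(vapply(got, paste, "", collapse = ","),
                      vapply(sets, paste, "", collapse = ","))
    }
  }
})

test_that("subunit size distribution counts cones per subunit", {
  expect_equal(subunit_size_distribution(diag(4)), c("1" = 4L))
  ind <- matrix(0, 5, 7)
  ind[1, 1:2] <- 1; ind[2, 3:4] <- 1; ind[3, 5] <- 1; ind[4, 6] <- 1
  ind[5, 7] <- 1
  expect_equal(subunit_size_distribution(ind), c("1" = 3L, "2" = 2L))
  set.seed(15)
  m <- random_model(9, 4, 16)
  d <- subunit_size_distribution(m)
  expect_equal(sum(d), 4L)
  expect_equal(sum(as.integer(names(d)) * d), 9L)
})

test_that("simulated spike counts are Poisson with the model rate", {
  m <- subunit_model(matrix(1, 1, 1), f = identity_spline(),
                     g = identity_spline(c(-8, 8)))
  # zero rate gives all-zero counts
  stim0 <- cone_stimulus(matrix(-2, 1, 200))
  expect_true(all(simulate_spikes(m, stim0, seed = 1) == 0))
  # constant rate 2: sample mean within 3 * sqrt(2 / T)
  stim2 <- cone_stimulus(matrix(2, 1, 4000))
  cts <- simulate_spikes(m, stim2, seed = 2)
  expect_lt(abs(mean(cts) - 2), 3 * sqrt(2 / 4000))
  # Fano factor near 1
  expect_lt(abs(stats::var(cts) / mean(cts) - 1), 0.1)
  # deterministic per seed
  expect_identical(cts, simulate_spikes(m, stim2, seed = 2))
})
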