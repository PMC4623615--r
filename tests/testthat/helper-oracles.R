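# Independent brute-force oracles: explicit scalar loops, no reuse of the
# package's vectorized forward-pass or metric code paths.

# forward pass by scalar loops over subunits, frames and cones
oracle_forward <- function(model, X, rate_floor = 1e-6) {
  S <- nrow(model$indicator); C <- ncol(model$indicator); Tn <- ncol(X)
  ffun <- stats::splinefun(model$f$node_x, model$f$node_y, method = "natural")
  gfun <- stats::splinefun(model$g$node_x, model$g$node_y, method = "natural")
  y <- matrix(0, S, Tn)
  z <- numeric(Tn)
  for (t in seq_len(Tn)) {
    for (s in seq_len(S)) {
      e <- 0
      for (cc in seq_len(C))
        e <- e + model$indicator[s, cc] * model$cone_weights[s, cc] * X[cc, t]
      y[s, t] <- ffun(e)
    }
    net <- 0
    for (s in seq_len(S)) net <- net + model$subunit_weights[s] * y[s, t]
    z[t] <- max(gfun(net), rate_floor)
  }
  list(y = y, z = z)
}

# term-by-term Poisson log-likelihood
oracle_loglik <- function(z, r) {
  tot <- 0
  for (t in seq_along(z)) tot <- tot + r[t] * log(z[t]) - z[t]
  tot
}

# direct-formula R^2
oracle_r2 <- function(pred, obs) {
  num <- 0; den <- 0; m <- sum(obs) / length(obs)
  for (t in seq_along(obs)) {
    num <- num + (pred[t] - obs[t])^2
    den <- den + (obs[t] - m)^2
  }
  1 - num / den
}

# least-squares slope through the origin
oracle_slope <- function(b, a) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    den <- den + a[i]^2
  }
  num / den
}

# top-k frames by squared prediction difference (stable sort oracle)
oracle_maxdiff <- function(pa, pb, fraction = 0.2) {
  d2 <- (pa - pb)^2
  k <- floor(fraction * length(d2))
  ord <- sort.list(d2, decreasing = TRUE, method = "radix")  # stable
  sort(ord[seq_len(k)])
}

# two-loop reimplementation of the reliability-adjusted R^2
oracle_adjusted_r2 <- function(trials, pred) {
  R <- nrow(trials)
  nums <- numeric(R); dens <- numeric(R)
  for (i in seq_len(R)) {
    other <- rep(0, ncol(trials))
    for (j in seq_len(R)) if (j != i) other <- other + trials[j, ]
    other <- other / (R - 1)
    nums[i] <- stats::cor(pred, trials[i, ])^2
    dens[i] <- stats::cor(trials[i, ], other)^2
  }
  mean(nums) / mean(dens)
}

# continuity defects of a spline at its interior nodes: for each interior
# node, the mismatch between the left interval's polynomial (value, first,
# second derivative) evaluated at the node and the right interval's
continuity_residuals <- function(sp) {
  cf <- spline_coefficients(sp)$intervals
  x <- sp$node_x
  res <- matrix(0, 6, 3)
  for (i in 1:6) {
    hh <- x[i + 1] - x[i]
    val_l <- cf[i, 1] + cf[i, 2] * hh + cf[i, 3] * hh^2 + cf[i, 4] * hh^3
    d1_l <- cf[i, 2] + 2 * cf[i, 3] * hh + 3 * cf[i, 4] * hh^2
    d2_l <- 2 * cf[i, 3] + 6 * cf[i, 4] * hh
    res[i, ] <- abs(c(val_l - cf[i + 1, 1], d1_l - cf[i + 1, 2],
                      d2_l - 2 * cf[i + 1, 3]))
  }
  res
}

# a random valid subunit model over C cones with a smooth f and g
random_model <- function(C, S, seed) {
  set.seed(seed)
  # random partition with every subunit non-empty
  assign_to <- c(seq_len(S), sample.int(S, C - S, replace = TRUE))
  assign_to <- sample(assign_to)
  ind <- matrix(0, S, C)
  for (cc in seq_len(C)) ind[assign_to[cc], cc] <- 1
  A <- ind * matrix(stats::runif(S * C, 0.2, 1), S, C)
  A <- A / rowSums(A)
  w <- stats::rnorm(S)
  f <- nl_spline(seq(-2, 2, length.out = 8), cumsum(stats::rnorm(8, 0.3, 0.3)))
  g <- nl_spline(seq(-4, 4, length.out = 8), log1p(exp(seq(-4, 4, length.out = 8))) *
                   stats::runif(1, 0.5, 2))
  subunit_model(ind, A, w, f, g)
}
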