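# Cubic-spline nonlinearities with eight node points.
#
# Both nonlinearities of the cascade (the subunit nonlinearity f and the
# output nonlinearity g) are piecewise cubic polynomials with eight nodes,
# constrained to have continuous first and second derivatives at the interior
# nodes. That constraint set is satisfied exactly by parameterizing each
# nonlinearity by its eight nodal values and taking the natural cubic
# interpolant, which is linear in the nodal values (so a basis matrix maps
# coefficients to values at arbitrary query points) and extrapolates linearly
# beyond the end nodes.

N_SPLINE_NODES <- 8L

#' Construct a cubic-spline nonlinearity
#'
#' Builds the smooth pointwise nonlinearity used for both the subunit stage
#' and the output stage of the subunit cascade model: a piecewise cubic
#' polynomial through eight node points with continuous first and second
#' derivatives everywhere, and linear extrapolation beyond the end nodes.
#' The free parameters are the eight nodal values.
#'
#' @param node_x Eight strictly increasing, finite node locations.
#' @param node_y Eight finite nodal values.
#' @return An object of class \code{"nl_spline"} with fields \code{node_x}
#'   and \code{node_y}.
#' @seealso [eval_spline()], [init_f()], [init_g()], [fit_spline_ml()]
#' @examples
#' sp <- nl_spline(seq(-2, 2, length.out = 8), pmin(seq(-2, 2, length.out = 8), 0))
#' eval_spline(sp, c(-1, 0, 1))
#' @export
nl_spline <- function(node_x, node_y) {
  node_x <- as.numeric(node_x)
  node_y <- as.numeric(node_y)
  if (length(node_x) != N_SPLINE_NODES || length(node_y) != N_SPLINE_NODES)
    stop("a nonlinearity spline uses exactly ", N_SPLINE_NODES, " node points")
  if (!all(is.finite(node_x)) || !all(is.finite(node_y)))
    stop("spline nodes and nodal values must be finite")
  if (any(diff(node_x) <= 0))
    stop("spline nodes must be strictly increasing")
  structure(list(node_x = node_x, node_y = node_y), class = "nl_spline")
}

#' @export
print.nl_spline <- function(x, ...) {
  cat("Cubic-spline nonlinearity (8 nodes, linear extrapolation)\n")
  cat("  node range: [", format(x$node_x[1]), ", ",
      format(x$node_x[length(x$node_x)]), "]\n", sep = "")
  print(rbind(x = x$node_x, value = x$node_y))
  invisible(x)
}

# closure evaluating the spline (and its derivatives via deriv=)
spline_fun <- function(spline) {
  stats::splinefun(spline$node_x, spline$node_y, method = "natural")
}

#' Evaluate a spline nonlinearity
#'
#' Evaluates an [nl_spline()] at arbitrary points. Inside the node range the
#' value is the C2 piecewise cubic; beyond the end nodes the end segments are
#' continued linearly. Matrix input returns a matrix of the same shape.
#'
#' @param spline An \code{nl_spline}.
#' @param v Numeric vector or matrix of query points.
#' @param deriv Derivative order 0, 1 or 2.
#' @return Values (or derivatives) with the same shape as \code{v}.
#' @export
eval_spline <- function(spline, v, deriv = 0L) {
  fn <- spline_fun(spline)
  out <- fn(as.vector(v), deriv = deriv)
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

#' Natural-spline basis matrix
#'
#' The natural cubic interpolant is linear in its nodal values, so evaluation
#' at any set of query points is \code{B \%*\% node_y} for a basis matrix
#' \code{B}. Used by the likelihood sub-problems that fit a nonlinearity with
#' the rest of the model held fixed.
#'
#' @param node_x Eight strictly increasing node locations.
#' @param v Query points (vector).
#' @return A \code{length(v) x 8} matrix.
#' @export
spline_basis <- function(node_x, v) {
  node_x <- as.numeric(node_x)
  if (length(node_x) != N_SPLINE_NODES || any(diff(node_x) <= 0))
    stop("node_x must be ", N_SPLINE_NODES, " strictly increasing values")
  v <- as.vector(v)
  B <- matrix(0, length(v), N_SPLINE_NODES)
  e <- numeric(N_SPLINE_NODES)
  for (i in seq_len(N_SPLINE_NODES)) {
    e[] <- 0; e[i] <- 1
    B[, i] <- stats::splinefun(node_x, e, method = "natural")(v)
  }
  B
}

#' Piecewise-cubic coefficients of a spline nonlinearity
#'
#' Returns, for each of the seven node intervals, the local cubic
#' coefficients \code{y(x) = a + b (x - x_i) + c (x - x_i)^2 + d (x - x_i)^3},
#' plus the linear extrapolation slopes at the two ends. Used for
#' serialization; [nl_spline()] reconstructs the same spline from nodes and
#' nodal values alone.
#'
#' @param spline An \code{nl_spline}.
#' @return A list with \code{intervals} (7 x 4 coefficient matrix) and
#'   \code{extrapolation_slopes} (length 2).
#' @export
spline_coefficients <- function(spline) {
  fn <- spline_fun(spline)
  x <- spline$node_x
  n <- length(x)
  a <- fn(x[-n])
  b <- fn(x[-n], deriv = 1)
  c2 <- fn(x[-n], deriv = 2) / 2
  h <- diff(x)
  d <- (fn(x[-1], deriv = 2) - fn(x[-n], deriv = 2)) / (6 * h)
  list(intervals = cbind(a = a, b = b, c = c2, d = d),
       extrapolation_slopes = c(fn(x[1], deriv = 1), fn(x[n], deriv = 1)))
}

#' Canonical initial nonlinearities
#'
#' \code{init_f()} is the initial subunit nonlinearity: negative half-wave
#' rectification, \code{min(v, 0)}, sampled at the nodes (the sign needed for
#' OFF-type responses is carried by the unconstrained subunit weights).
#' \code{init_g()} is the initial output nonlinearity: the softplus
#' \code{log(1 + exp(v))} sampled at the nodes.
#'
#' @param node_x Eight strictly increasing node locations; defaults span the
#'   typical standardized drive range.
#' @return An \code{nl_spline}.
#' @rdname init_nonlinearities
#' @export
init_f <- function(node_x = seq(-2, 2, length.out = N_SPLINE_NODES)) {
  nl_spline(node_x, pmin(node_x, 0))
}

#' @rdname init_nonlinearities
#' @export
init_g <- function(node_x = seq(-3, 3, length.out = N_SPLINE_NODES)) {
  nl_spline(node_x, log1p(exp(node_x)))
}

# Place 8 nodes equally spaced between the 1st and 99th percentiles of the
# empirical drive distribution (degenerate distributions get a unit pad).
place_nodes <- function(v) {
  q <- stats::quantile(as.vector(v), c(0.01, 0.99), names = FALSE)
  if (!all(is.finite(q))) stop("non-finite drive values in node placement")
  if (diff(q) < 1e-8) q <- q + c(-0.5, 0.5)
  seq(q[1], q[2], length.out = N_SPLINE_NODES)
}

#' Fit a spline nonlinearity by Poisson maximum likelihood
#'
#' Refits one of the two nonlinearities with the rest of the model held
#' fixed, maximizing the Poisson log-likelihood of the observed spike counts
#' over the eight nodal values. Nodes are placed between the 1st and 99th
#' percentiles of the current drive distribution. The returned spline never
#' has lower likelihood than the incoming one: if the optimizer fails to
#' improve, the incoming spline is returned and flagged.
#'
#' @param drive For the subunit nonlinearity, the S x T matrix of linear
#'   subunit drives; for the output nonlinearity, the length-T net drive
#'   vector.
#' @param counts Length-T non-negative integer spike counts.
#' @param downstream For a subunit-nonlinearity fit, a list with elements
#'   \code{w} (subunit weights) and \code{g} (the fixed output
#'   \code{nl_spline}); \code{NULL} for an output-nonlinearity fit.
#' @param spline_init Incoming \code{nl_spline} (warm start); defaults to
#'   [init_f()] or [init_g()] re-noded to the drive range.
#' @param rate_floor Minimum firing rate (spikes/frame) before the log.
#' @param maxit Maximum optimizer iterations.
#' @return The refitted \code{nl_spline}, with attributes \code{"logLik"}
#'   (achieved training log-likelihood) and \code{"improved"}.
#' @export
fit_spline_ml <- function(drive, counts, downstream = NULL, spline_init = NULL,
                          rate_floor = 1e-6, maxit = 50L) {
  counts <- as.numeric(counts)
  if (is.matrix(drive)) {
    if (is.null(downstream$w) || is.null(downstream$g))
      stop("fitting the subunit nonlinearity needs downstream$w and downstream$g")
    if (is.null(spline_init)) spline_init <- init_f(place_nodes(drive))
    res <- step_f(drive, spline_init, downstream$w, downstream$g, counts,
                  rate_floor, maxit)
  } else {
    if (is.null(spline_init)) spline_init <- init_g(place_nodes(drive))
    res <- step_g(as.numeric(drive), spline_init, counts, rate_floor, maxit)
  }
  structure(res$spline, logLik = res$ll, improved = res$improved)
}

# ---- internal likelihood sub-steps -------------------------------------

# log-likelihood for floored rates (factorial constant omitted)
ll_poisson <- function(z, counts) sum(counts * log(z)) - sum(z)

# Subunit-nonlinearity sub-step. E: S x T matrix of linear subunit drives.
# Optimizes the nodal values of f on nodes placed from E's percentiles;
# returns whichever of {incoming spline, optimized spline} has higher LL.
step_f <- function(E, f0, w, g, counts, rate_floor, maxit) {
  S <- nrow(E); Tn <- ncol(E)
  gfn <- spline_fun(g)
  nodes <- place_nodes(E)
  theta0 <- eval_spline(f0, nodes)
  # net drive is linear in the nodal values: net = M %*% theta
  M <- matrix(0, Tn, N_SPLINE_NODES)
  for (s in seq_len(S)) M <- M + w[s] * spline_basis(nodes, E[s, ])
  negll <- function(theta) {
    net <- drop(M %*% theta)
    z0 <- gfn(net)
    z <- pmax(z0, rate_floor)
    -(sum(counts * log(z)) - sum(z))
  }
  grad <- function(theta) {
    net <- drop(M %*% theta)
    z0 <- gfn(net)
    z <- pmax(z0, rate_floor)
    d <- (counts / z - 1) * gfn(net, deriv = 1)
    d[z0 < rate_floor] <- 0
    -drop(crossprod(M, d))
  }
  opt <- stats::optim(theta0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  ll_in <- forward_ll_f(E, f0, w, g, counts, rate_floor)
  ll_out <- -opt$value
  if (is.finite(ll_out) && ll_out > ll_in) {
    list(spline = nl_spline(nodes, opt$par), ll = ll_out, improved = TRUE)
  } else {
    list(spline = f0, ll = ll_in, improved = FALSE)
  }
}

forward_ll_f <- function(E, f, w, g, counts, rate_floor) {
  y <- eval_spline(f, E)
  net <- drop(crossprod(y, w))
  z <- pmax(eval_spline(g, net), rate_floor)
  ll_poisson(z, counts)
}

# Output-nonlinearity sub-step. net: length-T net drive.
step_g <- function(net, g0, counts, rate_floor, maxit) {
  nodes <- place_nodes(net)
  theta0 <- eval_spline(g0, nodes)
  B <- spline_basis(nodes, net)
  negll <- function(theta) {
    z0 <- drop(B %*% theta)
    z <- pmax(z0, rate_floor)
    -(sum(counts * log(z)) - sum(z))
  }
  grad <- function(theta) {
    z0 <- drop(B %*% theta)
    z <- pmax(z0, rate_floor)
    d <- counts / z - 1
    d[z0 < rate_floor] <- 0
    -drop(crossprod(B, d))
  }
  opt <- stats::optim(theta0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  ll_in <- ll_poisson(pmax(eval_spline(g0, net), rate_floor), counts)
  ll_out <- -opt$value
  if (is.finite(ll_out) && ll_out > ll_in) {
    list(spline = nl_spline(nodes, opt$par), ll = ll_out, improved = TRUE)
  } else {
    list(spline = g0, ll = ll_in, improved = FALSE)
  }
}
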