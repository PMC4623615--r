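# Model estimation: coordinate ascent over the continuous parameters
# (subunit weights w, within-subunit cone weights A, subunit nonlinearity f,
# with the output nonlinearity g refit once at the end), nested inside a
# greedy agglomerative search over cone-to-subunit assignments.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitting configuration
#'
#' @param train_fraction Fraction of frames used for fitting (default 0.8);
#'   the remainder is held out for evaluation.
#' @param max_rounds Maximum outer coordinate rounds (one round = w-step,
#'   A-step, f-step) for full-tolerance fits.
#' @param candidate_rounds Outer-round budget for warm-started candidate-merge
#'   refits during the greedy search.
#' @param rel_tol Relative log-likelihood change declaring convergence of the
#'   outer coordinate loop.
#' @param candidate_rel_tol Looser convergence tolerance used inside
#'   candidate-merge refits.
#' @param optim_maxit Per-sub-step optimizer iteration cap (full fits).
#' @param candidate_maxit Per-sub-step optimizer cap for candidate refits.
#' @param rate_floor Minimum firing rate in spikes/frame before the log.
#' @param test_block_seconds Target length of each held-out test block; test
#'   frames are contiguous blocks distributed across the recording rather
#'   than i.i.d. frames.
#' @param seed Integer seed threaded through the train/test split and any
#'   simulation performed with the same configuration.
#' @param keep_data Store the stimulus and counts inside the fit object (for
#'   \code{residuals}, \code{fitted}, \code{summary}).
#' @param verbose Print one line per greedy merge round.
#' @return A list of class \code{"fit_config"}.
#' @export
fit_config <- function(train_fraction = 0.8, max_rounds = 20L,
                       candidate_rounds = 5L, rel_tol = 1e-6,
                       candidate_rel_tol = 1e-5, optim_maxit = 50L,
                       candidate_maxit = 15L, rate_floor = 1e-6,
                       test_block_seconds = 60, seed = 1L,
                       keep_data = TRUE, verbose = FALSE) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  if (rate_floor <= 0) stop("rate_floor must be positive")
  structure(list(train_fraction = train_fraction,
                 max_rounds = as.integer(max_rounds),
                 candidate_rounds = as.integer(candidate_rounds),
                 rel_tol = rel_tol, candidate_rel_tol = candidate_rel_tol,
                 optim_maxit = as.integer(optim_maxit),
                 candidate_maxit = as.integer(candidate_maxit),
                 rate_floor = rate_floor,
                 test_block_seconds = test_block_seconds,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 keep_data = isTRUE(keep_data), verbose = isTRUE(verbose)),
            class = "fit_config")
}

#' Blocked train/test split
#'
#' Splits \code{n_frames} frames into a training set and held-out test
#' blocks. The test fraction is \code{1 - train_fraction}; test frames form
#' contiguous blocks of roughly \code{block_seconds} placed at random
#' positions within equal segments of the recording, so held-out data are
#' distributed throughout its duration (robust to slow nonstationarities).
#'
#' @param n_frames Total number of frames (at least 10).
#' @param frame_rate_hz Frame rate, used to convert block length to frames.
#' @param train_fraction Fraction of frames in the training set.
#' @param block_seconds Target test-block length in seconds.
#' @param seed Optional integer seed (deterministic per seed).
#' @return List with sorted integer vectors \code{train} and \code{test};
#'   disjoint and jointly exhaustive.
#' @export
split_train_test <- function(n_frames, frame_rate_hz = 12,
                             train_fraction = 0.8, block_seconds = 60,
                             seed = NULL) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 10L) stop("need at least 10 frames to split")
  if (!is.null(seed)) set.seed(seed)
  n_test <- round((1 - train_fraction) * n_frames)
  if (n_test < 1L) n_test <- 1L
  target <- max(1L, round(block_seconds * frame_rate_hz))
  n_blocks <- max(1L, round(n_test / target))
  sizes <- rep(n_test %/% n_blocks, n_blocks)
  extra <- n_test %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  # one test block placed uniformly at random inside each equal segment
  bounds <- floor(seq(0, n_frames, length.out = n_blocks + 1))
  test <- integer(0)
  for (b in seq_len(n_blocks)) {
    seg_start <- bounds[b] + 1L
    seg_len <- bounds[b + 1] - bounds[b]
    off <- if (seg_len > sizes[b]) sample.int(seg_len - sizes[b] + 1L, 1L) - 1L else 0L
    test <- c(test, seq.int(seg_start + off, length.out = min(sizes[b], seg_len)))
  }
  test <- sort(unique(test))
  list(train = setdiff(seq_len(n_frames), test), test = test)
}

stim_subset <- function(stim, idx) {
  cone_stimulus(stim$values[, idx, drop = FALSE], stim$frame_rate_hz,
                stim$cone_ids)
}

# ---- coordinate sub-steps ----------------------------------------------

# w-step: maximize LL over subunit weights with subunit outputs y fixed.
step_w <- function(y, w0, g, counts, rate_floor, maxit) {
  gfn <- spline_fun(g)
  negll <- function(w) {
    net <- drop(crossprod(y, w))
    z0 <- gfn(net)
    z <- pmax(z0, rate_floor)
    -(sum(counts * log(z)) - sum(z))
  }
  grad <- function(w) {
    net <- drop(crossprod(y, w))
    z0 <- gfn(net)
    z <- pmax(z0, rate_floor)
    d <- (counts / z - 1) * gfn(net, deriv = 1)
    d[z0 < rate_floor] <- 0
    -drop(y %*% d)
  }
  opt <- stats::optim(w0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  ll0 <- -negll(w0)
  if (is.finite(opt$value) && -opt$value > ll0)
    list(w = opt$par, ll = -opt$value, improved = TRUE)
  else list(w = w0, ll = ll0, improved = FALSE)
}

# A-step: maximize LL over within-subunit cone weights (positive, summing to
# 1 per subunit, via a softmax reparameterization). Only subunits with two or
# more cones have free parameters. Zero-variance stimuli leave the weights
# unidentifiable; the step then returns the initialization and flags it.
step_A <- function(ind, A0, X, f, w, g, counts, rate_floor, maxit) {
  free <- which(rowSums(ind) > 1)
  state <- function(A) {
    E <- (ind * A) %*% X
    y <- eval_spline(f, E)
    net <- drop(crossprod(y, w))
    z <- pmax(eval_spline(g, net), rate_floor)
    ll_poisson_raw(z, counts)
  }
  ll0 <- state(A0)
  if (length(free) == 0L)
    return(list(A = A0, ll = ll0, improved = FALSE, flag = NULL))
  if (all(apply(X, 1, stats::var) < 1e-12))
    return(list(A = A0, ll = ll0, improved = FALSE,
                flag = "A-step skipped: zero-variance stimulus leaves cone weights unidentifiable"))
  ffn <- spline_fun(f); gfn <- spline_fun(g)
  cones <- lapply(free, function(s) which(ind[s, ] == 1))
  npar <- lengths(cones)
  split_idx <- rep(seq_along(free), npar)
  # fixed rows contribute a constant to the net drive
  fixed <- setdiff(seq_len(nrow(ind)), free)
  net_base <- if (length(fixed)) {
    Efix <- (ind * A0)[fixed, , drop = FALSE] %*% X
    yfix <- ffn(Efix); dim(yfix) <- dim(Efix)
    drop(crossprod(yfix, w[fixed]))
  } else 0
  build_A <- function(xi) {
    A <- A0
    parts <- split(xi, split_idx)
    for (k in seq_along(free)) {
      e <- exp(parts[[k]] - max(parts[[k]]))
      A[free[k], cones[[k]]] <- e / sum(e)
    }
    A
  }
  pieces <- function(xi) {
    A <- build_A(xi)
    Ef <- (ind * A)[free, , drop = FALSE] %*% X
    yf <- ffn(Ef); dim(yf) <- dim(Ef)
    net <- net_base + drop(crossprod(yf, w[free]))
    list(A = A, Ef = Ef, net = net)
  }
  negll <- function(xi) {
    p <- pieces(xi)
    z0 <- gfn(p$net)
    z <- pmax(z0, rate_floor)
    -(sum(counts * log(z)) - sum(z))
  }
  grad <- function(xi) {
    p <- pieces(xi)
    z0 <- gfn(p$net)
    z <- pmax(z0, rate_floor)
    dnet <- (counts / z - 1) * gfn(p$net, deriv = 1)
    dnet[z0 < rate_floor] <- 0
    g_xi <- numeric(length(xi))
    pos <- 0L
    for (k in seq_along(free)) {
      s <- free[k]
      fp <- ffn(p$Ef[k, ], deriv = 1)
      dE <- w[s] * fp * dnet
      dA <- drop(X[cones[[k]], , drop = FALSE] %*% dE)
      a <- p$A[s, cones[[k]]]
      g_xi[pos + seq_along(a)] <- a * (dA - sum(a * dA))
      pos <- pos + length(a)
    }
    -g_xi
  }
  # warm start at the current weights (log of weights, floored)
  xi0 <- unlist(lapply(seq_along(free), function(k)
    log(pmax(A0[free[k], cones[[k]]], 1e-8))))
  opt <- stats::optim(xi0, negll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  if (is.finite(opt$value) && -opt$value > ll0)
    list(A = build_A(opt$par), ll = -opt$value, improved = TRUE, flag = NULL)
  else list(A = A0, ll = ll0, improved = FALSE, flag = NULL)
}

# as ll_poisson but without count validation (hot path)
ll_poisson_raw <- function(z, counts) sum(counts * log(z)) - sum(z)

# ---- continuous-parameter fit ------------------------------------------

#' Fit the continuous model parameters for a fixed assignment
#'
#' Coordinate ascent with the cone-to-subunit assignment held fixed: the
#' subunit weights w, the within-subunit cone weights A and the subunit
#' nonlinearity f are refit in that order each round, each sub-step
#' maximizing the training Poisson log-likelihood with the others fixed (so
#' the likelihood never decreases along the trace); the output nonlinearity g
#' is refit once at the end. Convergence is declared when the relative
#' log-likelihood change over a round falls below \code{rel_tol}.
#'
#' @param model Starting \code{subunit_model} (fixes the assignment).
#' @param stimulus Training \code{cone_stimulus}.
#' @param counts Training spike counts.
#' @param config A [fit_config()].
#' @param refit_g Refit the output nonlinearity after the coordinate loop.
#' @param rounds,maxit,rel_tol Optional overrides of the corresponding
#'   config values (used internally for warm-started candidate refits).
#' @return List with elements \code{model}, \code{logLik}, \code{trace}
#'   (data frame of per-sub-step log-likelihoods), \code{flags},
#'   \code{converged}.
#' @export
fit_continuous <- function(model, stimulus, counts, config = fit_config(),
                           refit_g = TRUE, rounds = NULL, maxit = NULL,
                           rel_tol = NULL) {
  stimulus <- check_stim(model, stimulus)
  counts <- spike_counts(counts, n_frames(stimulus))
  rounds <- rounds %||% config$max_rounds
  maxit <- maxit %||% config$optim_maxit
  rel_tol <- rel_tol %||% config$rel_tol
  floor <- config$rate_floor
  X <- stimulus$values
  ind <- model$indicator; A <- model$cone_weights
  w <- model$subunit_weights; f <- model$f; g <- model$g
  flags <- character(0)
  E <- (ind * A) %*% X
  y <- eval_spline(f, E)
  net <- drop(crossprod(y, w))
  ll <- ll_poisson_raw(pmax(eval_spline(g, net), floor), counts)
  tr_step <- "init"; tr_round <- 0L; tr_ll <- ll
  converged <- FALSE
  if (rounds > 0) for (round in seq_len(rounds)) {
    ll_round <- ll
    sw <- step_w(y, w, g, counts, floor, maxit)
    w <- sw$w; ll <- sw$ll
    tr_step <- c(tr_step, "w"); tr_round <- c(tr_round, round); tr_ll <- c(tr_ll, ll)
    sa <- step_A(ind, A, X, f, w, g, counts, floor, maxit)
    if (!is.null(sa$flag)) flags <- union(flags, sa$flag)
    if (sa$improved) {
      A <- sa$A
      E <- (ind * A) %*% X
      y <- eval_spline(f, E)
    }
    ll <- sa$ll
    tr_step <- c(tr_step, "A"); tr_round <- c(tr_round, round); tr_ll <- c(tr_ll, ll)
    sf <- step_f(E, f, w, g, counts, floor, maxit)
    if (sf$improved) {
      f <- sf$spline
      y <- eval_spline(f, E)
    }
    ll <- sf$ll
    tr_step <- c(tr_step, "f"); tr_round <- c(tr_round, round); tr_ll <- c(tr_ll, ll)
    if (abs(ll - ll_round) <= rel_tol * (abs(ll_round) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (refit_g) {
    net <- drop(crossprod(y, w))
    sg <- step_g(net, g, counts, floor, maxit)
    if (sg$improved) g <- sg$spline
    ll <- sg$ll
    tr_step <- c(tr_step, "g"); tr_round <- c(tr_round, NA_integer_); tr_ll <- c(tr_ll, ll)
  }
  list(model = subunit_model(ind, A, w, f, g, cone_ids = stimulus$cone_ids),
       logLik = ll,
       trace = data.frame(step = tr_step, round = tr_round, logLik = tr_ll),
       flags = flags, converged = converged)
}

# Warm start for a merged pair: cone weights are the concatenation of the two
# subunits' weights scaled by |w|, renormalized to sum to 1; the merged
# subunit weight is the sum of the two (keeps the net drive roughly unchanged
# when the signs agree).
merge_warm_start <- function(model, s1, s2) {
  lo <- min(s1, s2); hi <- max(s1, s2)
  ind <- model$indicator; A <- model$cone_weights; w <- model$subunit_weights
  ind_new <- merge_subunits(ind, lo, hi)
  A_new <- A[-hi, , drop = FALSE]
  row <- abs(w[lo]) * A[lo, ] + abs(w[hi]) * A[hi, ]
  if (sum(row) <= 0) row <- ind[lo, ] + ind[hi, ]
  A_new[lo, ] <- row / sum(row)
  w_new <- w[-hi]
  w_new[lo] <- w[lo] + w[hi]
  subunit_model(ind_new, A_new, w_new, model$f, model$g,
                cone_ids = model$cone_ids)
}

#' Fit the hierarchical subunit model
#'
#' The full estimation procedure. The assignment is initialized to the
#' identity (one cone per subunit), the continuous parameters are fit by
#' coordinate ascent ([fit_continuous()]), and subunits are then merged
#' greedily: at each round every possible pairing of two subunits is
#' evaluated by refitting the continuous parameters (warm-started from the
#' current fit), and the best pair is merged if and only if it improves the
#' maximized training likelihood over the unmerged model. The search stops
#' when no pairing improves the likelihood (at most C - 1 merges), after
#' which the output nonlinearity g is refit once. Fitting uses the training
#' portion of a blocked train/test split ([split_train_test()]).
#'
#' @param stimulus A \code{cone_stimulus} (C cones x T frames).
#' @param counts Length-T non-negative integer spike counts.
#' @param config A [fit_config()]; \code{config$seed} makes the split (and
#'   hence the whole fit) deterministic.
#' @return An object of class \code{"subunit_fit"}: fields \code{model}
#'   (the fitted [subunit_model()]), \code{logLik} (training), \code{trace}
#'   (per-sub-step log-likelihood trace along the accepted path),
#'   \code{merge_history} (one row per greedy round), \code{train}/
#'   \code{test} frame indices, \code{flags}, and (if kept) the data.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{logLik}, \code{plot},
#'   \code{simulate}.
#' @examples
#' \donttest{
#' truth <- example_ground_truth(n_cones = 4, sizes = c(2, 1, 1))
#' stim <- white_noise_cone_stimulus(4, duration_min = 2, seed = 1)
#' cts <- simulate_spikes(truth, stim, seed = 2)
#' fit <- fit_subunit_model(stim, cts, fit_config(seed = 3))
#' fit
#' }
#' @export
fit_subunit_model <- function(stimulus, counts, config = fit_config()) {
  cl <- match.call()
  if (!inherits(stimulus, "cone_stimulus")) stimulus <- cone_stimulus(stimulus)
  counts <- spike_counts(counts, n_frames(stimulus))
  C <- n_cones(stimulus)
  split <- split_train_test(n_frames(stimulus), stimulus$frame_rate_hz,
                            config$train_fraction, config$test_block_seconds,
                            seed = config$seed)
  tr_stim <- stim_subset(stimulus, split$train)
  tr_counts <- counts[split$train]
  model <- init_subunit_model(tr_stim)
  fit <- fit_continuous(model, tr_stim, tr_counts, config, refit_g = FALSE)
  trace <- cbind(phase = "initial", fit$trace)
  flags <- fit$flags
  history <- list()
  round_i <- 0L
  repeat {
    S <- nrow(fit$model$indicator)
    if (S == 1L) break
    round_i <- round_i + 1L
    # give the unmerged model the same incremental budget the candidates
    # receive, so the accept/reject comparison is not biased by one side
    # having had more ascent iterations
    cont <- fit_continuous(fit$model, tr_stim, tr_counts, config,
                           refit_g = FALSE,
                           rounds = config$candidate_rounds,
                           maxit = config$candidate_maxit,
                           rel_tol = config$candidate_rel_tol)
    if (cont$logLik > fit$logLik) fit <- cont
    pairs <- utils::combn(S, 2L)
    best_ll <- -Inf; best_fit <- NULL; best_pair <- c(NA, NA)
    for (k in seq_len(ncol(pairs))) {
      cand <- merge_warm_start(fit$model, pairs[1, k], pairs[2, k])
      cfit <- fit_continuous(cand, tr_stim, tr_counts, config,
                             refit_g = FALSE,
                             rounds = config$candidate_rounds,
                             maxit = config$candidate_maxit,
                             rel_tol = config$candidate_rel_tol)
      if (cfit$logLik > best_ll) {
        best_ll <- cfit$logLik
        best_fit <- cfit
        best_pair <- pairs[, k]
      }
    }
    accepted <- best_ll > fit$logLik
    history[[round_i]] <- data.frame(
      round = round_i, n_candidates = ncol(pairs),
      s1 = best_pair[1], s2 = best_pair[2],
      delta_logLik = best_ll - fit$logLik, accepted = accepted)
    if (config$verbose)
      message(sprintf("merge round %d: %d candidates, best (%d,%d) dLL=%.4g %s",
                      round_i, ncol(pairs), best_pair[1], best_pair[2],
                      best_ll - fit$logLik,
                      if (accepted) "accepted" else "rejected"))
    if (!accepted) break
    # re-estimate the accepted merged model to full tolerance, both by
    # continuing the warm-started candidate (a monotone continuation of the
    # trace) and from a fresh initialization (guards against local optima
    # inherited through the warm-started path); keep the better
    warm <- fit_continuous(best_fit$model, tr_stim, tr_counts, config,
                           refit_g = FALSE)
    fresh <- fit_continuous(init_model_at(best_fit$model$indicator, tr_stim),
                            tr_stim, tr_counts, config, refit_g = FALSE)
    trace <- rbind(trace, cbind(phase = paste0("merge", round_i), warm$trace))
    if (fresh$logLik > warm$logLik) {
      fit <- fresh
      # the accepted model jumps to the fresh optimum (higher likelihood);
      # recorded as a single reinit step so the trace tracks accepted models
      trace <- rbind(trace, data.frame(phase = paste0("merge", round_i),
                                       step = "reinit", round = NA_integer_,
                                       logLik = fresh$logLik))
    } else fit <- warm
    flags <- union(flags, fit$flags)
  }
  # g is refit once, after the assignment search terminates
  fit <- fit_continuous(fit$model, tr_stim, tr_counts, config,
                        refit_g = TRUE, rounds = 0L)
  trace <- rbind(trace, cbind(phase = "final", fit$trace))
  merge_history <- if (length(history)) do.call(rbind, history) else
    data.frame(round = integer(0), n_candidates = integer(0),
               s1 = integer(0), s2 = integer(0),
               delta_logLik = numeric(0), accepted = logical(0))
  out <- list(model = fit$model, logLik = fit$logLik, trace = trace,
              merge_history = merge_history, train = split$train,
              test = split$test, config = config, flags = flags,
              structure = "subunit", call = cl)
  if (config$keep_data) {
    out$stimulus <- stimulus
    out$counts <- counts
  }
  class(out) <- "subunit_fit"
  out
}

# Freshly initialized model at a given assignment: w and A all ones (A rows
# renormalized), f negative half-wave rectification over the empirical drive
# range, g softplus over the resulting net-drive range.
init_model_at <- function(indicator, tr_stim) {
  X <- tr_stim$values
  S <- nrow(indicator)
  A0 <- indicator / rowSums(indicator)
  E0 <- A0 %*% X
  f0 <- init_f(place_nodes(E0))
  w0 <- rep(1, S)
  net0 <- drop(crossprod(eval_spline(f0, E0), w0))
  g0 <- init_g(place_nodes(net0))
  subunit_model(indicator, A0, w0, f0, g0, cone_ids = tr_stim$cone_ids)
}

init_subunit_model <- function(tr_stim) {
  init_model_at(diag(nrow(tr_stim$values)), tr_stim)
}

#' Fit the single-cone subunit model
#'
#' The restriction of the subunit model with identity assignment (every cone
#' its own subunit) but a free subunit nonlinearity: no merge search, only
#' the continuous coordinate ascent.
#'
#' @inheritParams fit_subunit_model
#' @return A \code{"subunit_fit"} with \code{structure = "single_cone"}.
#' @export
fit_single_cone_model <- function(stimulus, counts, config = fit_config()) {
  cl <- match.call()
  if (!inherits(stimulus, "cone_stimulus")) stimulus <- cone_stimulus(stimulus)
  counts <- spike_counts(counts, n_frames(stimulus))
  split <- split_train_test(n_frames(stimulus), stimulus$frame_rate_hz,
                            config$train_fraction, config$test_block_seconds,
                            seed = config$seed)
  tr_stim <- stim_subset(stimulus, split$train)
  tr_counts <- counts[split$train]
  fit <- fit_continuous(init_subunit_model(tr_stim), tr_stim, tr_counts,
                        config, refit_g = TRUE)
  out <- list(model = fit$model, logLik = fit$logLik,
              trace = cbind(phase = "initial", fit$trace),
              merge_history = data.frame(round = integer(0),
                                         n_candidates = integer(0),
                                         s1 = integer(0), s2 = integer(0),
                                         delta_logLik = numeric(0),
                                         accepted = logical(0)),
              train = split$train, test = split$test, config = config,
              flags = fit$flags, structure = "single_cone", call = cl)
  if (config$keep_data) {
    out$stimulus <- stimulus
    out$counts <- counts
  }
  class(out) <- "subunit_fit"
  out
}

#' Fit the LN model
#'
#' Linear-nonlinear reduction: a single unconstrained weight per cone
#' followed by the output nonlinearity. Weights are fit by the same Poisson
#' maximum-likelihood machinery (repeated weight steps with g fixed at its
#' softplus initialization), and g is refit once at the end.
#'
#' @inheritParams fit_subunit_model
#' @return An object of class \code{"ln_fit"} with fields \code{model} (an
#'   [ln_model()]), \code{logLik}, \code{trace}, \code{train}, \code{test}.
#' @export
fit_ln_model <- function(stimulus, counts, config = fit_config()) {
  cl <- match.call()
  if (!inherits(stimulus, "cone_stimulus")) stimulus <- cone_stimulus(stimulus)
  counts <- spike_counts(counts, n_frames(stimulus))
  split <- split_train_test(n_frames(stimulus), stimulus$frame_rate_hz,
                            config$train_fraction, config$test_block_seconds,
                            seed = config$seed)
  X <- stimulus$values[, split$train, drop = FALSE]
  tr_counts <- counts[split$train]
  floor <- config$rate_floor
  C <- nrow(X)
  w <- rep(1, C)
  g <- init_g(place_nodes(drop(crossprod(X, w))))
  ll <- ll_poisson_raw(pmax(eval_spline(g, drop(crossprod(X, w))), floor),
                       tr_counts)
  tr_step <- "init"; tr_ll <- ll
  for (round in seq_len(config$max_rounds)) {
    ll_round <- ll
    sw <- step_w(X, w, g, tr_counts, floor, config$optim_maxit)
    w <- sw$w; ll <- sw$ll
    tr_step <- c(tr_step, "w"); tr_ll <- c(tr_ll, ll)
    if (abs(ll - ll_round) <= config$rel_tol * (abs(ll_round) + 1)) break
  }
  net <- drop(crossprod(X, w))
  sg <- step_g(net, g, tr_counts, floor, config$optim_maxit)
  if (sg$improved) g <- sg$spline
  ll <- sg$ll
  tr_step <- c(tr_step, "g"); tr_ll <- c(tr_ll, ll)
  out <- list(model = ln_model(w, g, cone_ids = stimulus$cone_ids),
              logLik = ll,
              trace = data.frame(step = tr_step, logLik = tr_ll),
              train = split$train, test = split$test, config = config,
              call = cl)
  if (config$keep_data) {
    out$stimulus <- stimulus
    out$counts <- counts
  }
  class(out) <- "ln_fit"
  out
}

# ---- methods ------------------------------------------------------------

#' @export
print.subunit_fit <- function(x, ...) {
  sz <- rowSums(x$model$indicator)
  cat("Hierarchical subunit model fit",
      if (x$structure == "single_cone") "(single-cone restriction)" else "",
      "\n")
  cat("  cones:", ncol(x$model$indicator),
      " subunits:", nrow(x$model$indicator),
      " sizes:", paste(sort(sz, decreasing = TRUE), collapse = ","), "\n")
  cat("  accepted merges:", sum(x$merge_history$accepted),
      " training logLik:", format(x$logLik, digits = 8), "\n")
  cat("  train/test frames:", length(x$train), "/", length(x$test), "\n")
  invisible(x)
}

#' @export
summary.subunit_fit <- function(object, ...) {
  out <- list(n_cones = ncol(object$model$indicator),
              n_subunits = nrow(object$model$indicator),
              size_distribution = subunit_size_distribution(object$model),
              n_merges = sum(object$merge_history$accepted),
              logLik_train = object$logLik,
              subunit_weights = object$model$subunit_weights,
              flags = object$flags)
  if (!is.null(object$stimulus)) {
    test_stim <- stim_subset(object$stimulus, object$test)
    pred <- predict(object$model, test_stim)
    out$r_squared_test <- r_squared(pred, object$counts[object$test])
  }
  class(out) <- "summary.subunit_fit"
  out
}

#' @export
print.summary.subunit_fit <- function(x, ...) {
  cat("Subunit model fit:", x$n_cones, "cones,", x$n_subunits, "subunits\n")
  cat("  cones per subunit: ")
  print(x$size_distribution)
  cat("  accepted merges:", x$n_merges, "\n")
  cat("  training logLik:", format(x$logLik_train, digits = 8), "\n")
  if (!is.null(x$r_squared_test))
    cat("  held-out R^2:", format(x$r_squared_test, digits = 4), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.subunit_fit <- function(object, ...) {
  list(subunit_weights = object$model$subunit_weights,
       cone_weights = object$model$cone_weights,
       assignment = object$model$indicator)
}

#' @export
predict.subunit_fit <- function(object, newdata = NULL,
                                type = c("rate", "subunit"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$stimulus))
      stop("no stored stimulus; supply newdata or fit with keep_data = TRUE")
    newdata <- object$stimulus
  }
  predict(object$model, newdata, type = type)
}

#' @export
fitted.subunit_fit <- function(object, ...) predict(object)

#' @export
residuals.subunit_fit <- function(object,
                                  type = c("pearson", "response", "deviance"),
                                  ...) {
  type <- match.arg(type)
  if (is.null(object$stimulus))
    stop("no stored data; fit with keep_data = TRUE")
  z <- predict(object)
  r <- object$counts
  switch(type,
         response = r - z,
         pearson = (r - z) / sqrt(z),
         deviance = {
           d <- 2 * (ifelse(r > 0, r * log(r / z), 0) - (r - z))
           sign(r - z) * sqrt(pmax(d, 0))
         })
}

#' @export
logLik.subunit_fit <- function(object, ...) {
  S <- nrow(object$model$indicator)
  df <- S + sum(rowSums(object$model$indicator) - 1) + 2 * N_SPLINE_NODES
  structure(object$logLik, df = df, nobs = length(object$train),
            class = "logLik")
}

#' @export
simulate.subunit_fit <- function(object, nsim = 1, seed = NULL,
                                 stimulus = NULL, ...) {
  if (is.null(stimulus)) {
    if (is.null(object$stimulus)) stop("supply a stimulus to simulate from")
    stimulus <- object$stimulus
  }
  simulate(object$model, nsim = nsim, seed = seed, stimulus = stimulus)
}

#' @export
plot.subunit_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  f <- x$model$f; g <- x$model$g
  vx <- seq(f$node_x[1], f$node_x[8], length.out = 200)
  graphics::plot(vx, eval_spline(f, vx), type = "l", xlab = "subunit input",
       ylab = "f", main = "Subunit nonlinearity")
  graphics::points(f$node_x, f$node_y, pch = 16, cex = 0.6)
  vx <- seq(g$node_x[1], g$node_x[8], length.out = 200)
  graphics::plot(vx, eval_spline(g, vx), type = "l", xlab = "net drive",
       ylab = "g (spikes/frame)", main = "Output nonlinearity")
  graphics::points(g$node_x, g$node_y, pch = 16, cex = 0.6)
  graphics::plot(seq_along(x$trace$logLik), x$trace$logLik, type = "b", pch = 16,
       cex = 0.5, xlab = "sub-step", ylab = "training logLik",
       main = "Optimization trace")
  sz <- rowSums(x$model$indicator)
  graphics::barplot(table(sz), xlab = "cones per subunit", ylab = "subunits",
                    main = "Subunit sizes")
  invisible(x)
}

#' @export
print.ln_fit <- function(x, ...) {
  cat("LN model fit:", length(x$model$weights), "cone weights\n")
  cat("  training logLik:", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' @export
coef.ln_fit <- function(object, ...) object$model$weights

#' @export
predict.ln_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$stimulus))
      stop("no stored stimulus; supply newdata or fit with keep_data = TRUE")
    newdata <- object$stimulus
  }
  predict(object$model, newdata)
}

#' @export
logLik.ln_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$model$weights) + N_SPLINE_NODES,
            nobs = length(object$train), class = "logLik")
}
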