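# Domain types and the forward model: cone inputs -> subunit drives ->
# firing rate, the Poisson log-likelihood, and the LN reduction.

#' Cone-input stimulus
#'
#' The stimulus as seen by the model: one row per cone, one column per
#' stimulus frame, in signed contrast units (mean-subtracted). This is the
#' result of integrating a pixel stimulus against each cone's Gaussian
#' aperture, or the direct output of the synthetic generators.
#'
#' @param values C x T numeric matrix of per-cone contrast inputs.
#' @param frame_rate_hz Stimulus frame rate in Hz (> 0); spike counts are
#'   binned at this resolution. Default 12 Hz (83 ms bins).
#' @param cone_ids Optional length-C identifier vector (default
#'   \code{"c1"..."cC"}).
#' @return An object of class \code{"cone_stimulus"}.
#' @examples
#' stim <- cone_stimulus(matrix(c(1, -1), 2, 5), frame_rate_hz = 12)
#' n_cones(stim); n_frames(stim)
#' @export
cone_stimulus <- function(values, frame_rate_hz = 12, cone_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("stimulus must have at least one cone and one frame")
  if (!all(is.finite(values))) stop("stimulus values must be finite")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0)
    stop("frame_rate_hz must be a single positive number")
  if (is.null(cone_ids)) cone_ids <- paste0("c", seq_len(nrow(values)))
  if (length(cone_ids) != nrow(values))
    stop("cone_ids length must equal the number of cones")
  structure(list(values = values, frame_rate_hz = frame_rate_hz,
                 cone_ids = as.character(cone_ids)),
            class = "cone_stimulus")
}

#' @rdname cone_stimulus
#' @param stim A \code{cone_stimulus}.
#' @export
n_cones <- function(stim) nrow(stim$values)

#' @rdname cone_stimulus
#' @export
n_frames <- function(stim) ncol(stim$values)

#' @export
print.cone_stimulus <- function(x, ...) {
  cat("Cone stimulus:", n_cones(x), "cones x", n_frames(x), "frames @",
      x$frame_rate_hz, "Hz (",
      format(n_frames(x) / x$frame_rate_hz / 60, digits = 3), "min )\n")
  invisible(x)
}

#' Spike counts aligned to stimulus frames
#'
#' Validates a vector of per-frame spike counts (non-negative integers).
#'
#' @param counts Numeric vector of non-negative integer counts.
#' @param n_frames Optional expected length (frames of the paired stimulus).
#' @return An integer vector.
#' @export
spike_counts <- function(counts, n_frames = NULL) {
  counts <- as.vector(counts)
  if (!is.numeric(counts) || !all(is.finite(counts)))
    stop("spike counts must be finite numbers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spike counts must be non-negative integers")
  if (!is.null(n_frames) && length(counts) != n_frames)
    stop("spike count length (", length(counts),
         ") does not match the stimulus frame count (", n_frames, ")")
  as.integer(round(counts))
}

#' Cone-to-subunit assignment matrix
#'
#' Validates the binary S x C indicator matrix assigning cones to subunits.
#' Subunits are non-overlapping: every column sums to exactly 1 (each cone
#' belongs to exactly one subunit) and every row has at least one cone, so S
#' ranges from 1 (a single subunit pooling all cones) to C (single-cone
#' subunits).
#'
#' @param indicator S x C matrix of 0/1 values.
#' @return The validated 0/1 matrix.
#' @seealso [merge_subunits()]
#' @export
subunit_assignment <- function(indicator) {
  indicator <- as.matrix(indicator)
  storage.mode(indicator) <- "double"
  if (!all(indicator %in% c(0, 1)))
    stop("assignment indicator must be binary")
  if (any(colSums(indicator) != 1))
    stop("each cone must belong to exactly one subunit (column sums must be 1)")
  if (any(rowSums(indicator) < 1))
    stop("each subunit must contain at least one cone")
  indicator
}

#' Within-subunit cone weight matrix
#'
#' Validates the non-negative S x C weight matrix A giving each cone's weight
#' within its subunit. Weights are supported only where the assignment
#' indicator is 1 and each row sums to 1 over its support (tolerance 1e-9).
#'
#' @param weights S x C non-negative matrix.
#' @param indicator Matching assignment indicator (see
#'   [subunit_assignment()]).
#' @return The validated weight matrix.
#' @export
cone_weight_matrix <- function(weights, indicator) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  indicator <- subunit_assignment(indicator)
  if (!all(dim(weights) == dim(indicator)))
    stop("cone weight matrix and assignment indicator dimensions differ")
  if (any(weights < 0)) stop("cone weights must be non-negative")
  if (any(weights[indicator == 0] != 0))
    stop("cone weights must vanish outside the assignment support")
  rs <- rowSums(weights * indicator)
  if (any(abs(rs - 1) > 1e-9))
    stop("cone weights within each subunit must sum to 1")
  weights
}

#' Hierarchical subunit model
#'
#' The full LNLN-Poisson cascade: cone inputs are pooled linearly within
#' non-overlapping subunits (indicator I, positive within-subunit weights A
#' summing to 1 per subunit), passed through a shared subunit nonlinearity f,
#' weighted by unconstrained subunit weights w, summed, and passed through
#' the output nonlinearity g, which gives the Poisson firing rate in
#' spikes/frame.
#'
#' @param indicator S x C binary assignment matrix (cones to subunits).
#' @param cone_weights S x C non-negative within-subunit weights; default:
#'   indicator rows normalized to sum to 1.
#' @param subunit_weights Length-S numeric subunit weights (unconstrained
#'   sign and magnitude); default all 1.
#' @param f Subunit nonlinearity ([nl_spline()]); default [init_f()].
#' @param g Output nonlinearity; default [init_g()].
#' @param cone_ids Optional cone identifiers.
#' @return An object of class \code{"subunit_model"}.
#' @seealso [predict.subunit_model()], [firing_rate()], [fit_subunit_model()]
#' @export
subunit_model <- function(indicator, cone_weights = NULL,
                          subunit_weights = NULL, f = init_f(), g = init_g(),
                          cone_ids = NULL) {
  indicator <- subunit_assignment(indicator)
  S <- nrow(indicator); C <- ncol(indicator)
  if (is.null(cone_weights))
    cone_weights <- indicator / rowSums(indicator)
  cone_weights <- cone_weight_matrix(cone_weights, indicator)
  if (is.null(subunit_weights)) subunit_weights <- rep(1, S)
  subunit_weights <- as.numeric(subunit_weights)
  if (length(subunit_weights) != S || !all(is.finite(subunit_weights)))
    stop("subunit_weights must be ", S, " finite values")
  if (!inherits(f, "nl_spline") || !inherits(g, "nl_spline"))
    stop("f and g must be nl_spline nonlinearities")
  if (is.null(cone_ids)) cone_ids <- paste0("c", seq_len(C))
  structure(list(indicator = indicator, cone_weights = cone_weights,
                 subunit_weights = subunit_weights, f = f, g = g,
                 cone_ids = as.character(cone_ids)),
            class = "subunit_model")
}

#' @export
print.subunit_model <- function(x, ...) {
  sz <- rowSums(x$indicator)
  cat("Subunit model:", ncol(x$indicator), "cones in", nrow(x$indicator),
      "subunits (sizes:", paste(sort(sz, decreasing = TRUE), collapse = ","),
      ")\n")
  cat("  subunit weights:", paste(format(x$subunit_weights, digits = 3),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Pooling matrix U = I * A
#'
#' The effective cone-to-subunit weight matrix, the elementwise product of
#' the binary assignment and the within-subunit weights.
#'
#' @param model A \code{subunit_model}.
#' @return S x C numeric matrix.
#' @export
pooling_matrix <- function(model) model$indicator * model$cone_weights

check_stim <- function(model, stim) {
  if (!inherits(stim, "cone_stimulus")) stim <- cone_stimulus(stim)
  if (n_cones(stim) != ncol(model$indicator))
    stop("stimulus has ", n_cones(stim), " cones but the model expects ",
         ncol(model$indicator))
  stim
}

#' Subunit outputs
#'
#' First cascade stage: the S x T matrix of subunit responses
#' \code{y[s, t] = f(sum_c U[s, c] x[c, t])} with \code{U = I * A}.
#'
#' @param model A \code{subunit_model}.
#' @param stim A \code{cone_stimulus} with matching cone count.
#' @return S x T numeric matrix of post-nonlinearity subunit outputs.
#' @export
subunit_drive <- function(model, stim) {
  stim <- check_stim(model, stim)
  E <- pooling_matrix(model) %*% stim$values
  eval_spline(model$f, E)
}

#' Model firing rate
#'
#' Full forward pass: subunit outputs are weighted by \code{w}, summed, and
#' passed through the output nonlinearity \code{g}; the result is floored at
#' \code{rate_floor} so the Poisson log-likelihood is always defined.
#'
#' @inheritParams subunit_drive
#' @param rate_floor Minimum rate in spikes/frame (default 1e-6).
#' @return Length-T vector of non-negative firing rates (spikes/frame).
#' @export
firing_rate <- function(model, stim, rate_floor = 1e-6) {
  y <- subunit_drive(model, stim)
  net <- drop(crossprod(y, model$subunit_weights))
  if (!all(is.finite(net)))
    stop("non-finite net drive in forward pass (check weights and stimulus)")
  z <- eval_spline(model$g, net)
  if (!all(is.finite(z)))
    stop("non-finite firing rate from output nonlinearity")
  pmax(z, rate_floor)
}

#' Poisson log-likelihood of spike counts
#'
#' \code{sum(r * log(z)) - sum(z)} for rates z (spikes/frame) and counts r;
#' the count-factorial constant is omitted, so values are comparable across
#' models on the same data but are not full log-probabilities.
#'
#' @param rates Length-T positive rate vector (spikes/frame).
#' @param counts Length-T non-negative integer counts.
#' @return A finite scalar; larger is better.
#' @export
poisson_log_likelihood <- function(rates, counts) {
  counts <- spike_counts(counts, length(rates))
  if (any(rates <= 0)) stop("rates must be positive (apply the rate floor first)")
  ll <- sum(counts * log(rates)) - sum(rates)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' Linear-nonlinear (LN) model
#'
#' The reduction of the subunit cascade with one linear stage: a single
#' weighted sum of cone inputs followed by the output nonlinearity. The
#' subunit model reduces to it when I and A are identity matrices and f is
#' linear.
#'
#' @param weights Length-C cone weight vector (unconstrained).
#' @param g Output nonlinearity ([nl_spline()]).
#' @param cone_ids Optional cone identifiers.
#' @return An object of class \code{"ln_model"}.
#' @export
ln_model <- function(weights, g = init_g(), cone_ids = NULL) {
  weights <- as.numeric(weights)
  if (!all(is.finite(weights))) stop("LN weights must be finite")
  if (!inherits(g, "nl_spline")) stop("g must be an nl_spline")
  if (is.null(cone_ids)) cone_ids <- paste0("c", seq_along(weights))
  structure(list(weights = weights, g = g, cone_ids = as.character(cone_ids)),
            class = "ln_model")
}

#' @export
print.ln_model <- function(x, ...) {
  cat("LN model:", length(x$weights), "cone weights + output nonlinearity\n")
  invisible(x)
}

#' LN model firing rate
#'
#' @param model An \code{ln_model}.
#' @param stim A \code{cone_stimulus}.
#' @param rate_floor Minimum rate in spikes/frame.
#' @return Length-T firing-rate vector (spikes/frame).
#' @export
ln_predict <- function(model, stim, rate_floor = 1e-6) {
  if (!inherits(stim, "cone_stimulus")) stim <- cone_stimulus(stim)
  if (n_cones(stim) != length(model$weights))
    stop("stimulus cone count does not match the LN weight vector")
  net <- drop(crossprod(stim$values, model$weights))
  z <- eval_spline(model$g, net)
  if (!all(is.finite(z))) stop("non-finite firing rate from output nonlinearity")
  pmax(z, rate_floor)
}

#' @param object A model object.
#' @param stimulus A \code{cone_stimulus}.
#' @param type \code{"rate"} for firing rates, \code{"subunit"} for the S x T
#'   subunit outputs (subunit model only).
#' @param rate_floor Minimum rate in spikes/frame.
#' @param ... Unused.
#' @rdname firing_rate
#' @export
predict.subunit_model <- function(object, stimulus,
                                  type = c("rate", "subunit"),
                                  rate_floor = 1e-6, ...) {
  type <- match.arg(type)
  if (type == "rate") firing_rate(object, stimulus, rate_floor)
  else subunit_drive(object, stimulus)
}

#' @rdname ln_predict
#' @param object An \code{ln_model}.
#' @param stimulus A \code{cone_stimulus}.
#' @param ... Unused.
#' @export
predict.ln_model <- function(object, stimulus, rate_floor = 1e-6, ...) {
  ln_predict(object, stimulus, rate_floor)
}

#' Merge two subunits
#'
#' Replaces subunits \code{s1} and \code{s2} of an assignment by their union;
#' the number of subunits decreases by exactly one and every cone still
#' belongs to exactly one subunit.
#'
#' @param indicator S x C assignment matrix ([subunit_assignment()]).
#' @param s1,s2 Distinct row indices to merge.
#' @return The merged (S-1) x C assignment matrix.
#' @export
merge_subunits <- function(indicator, s1, s2) {
  indicator <- subunit_assignment(indicator)
  S <- nrow(indicator)
  if (!(s1 %in% seq_len(S)) || !(s2 %in% seq_len(S)) || s1 == s2)
    stop("s1 and s2 must be distinct valid subunit indices")
  lo <- min(s1, s2); hi <- max(s1, s2)
  indicator[lo, ] <- indicator[lo, ] + indicator[hi, ]
  subunit_assignment(indicator[-hi, , drop = FALSE])
}

#' Distribution of subunit sizes
#'
#' Tabulates cones-per-subunit for a fitted or constructed model (the summary
#' used to compare functional subunits with the anatomical convergence of
#' cones onto midget bipolar cells).
#'
#' @param x A \code{subunit_model}, \code{subunit_fit}, or assignment matrix.
#' @return Named integer vector: names are subunit sizes, values are counts;
#'   the counts sum to the number of subunits.
#' @export
subunit_size_distribution <- function(x) {
  if (inherits(x, "subunit_fit")) x <- x$model
  ind <- if (inherits(x, "subunit_model")) x$indicator else subunit_assignment(x)
  sz <- rowSums(ind)
  tab <- table(factor(sz, levels = sort(unique(sz))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Simulate Poisson spike counts from a model
#'
#' Draws independent Poisson counts per frame with the model's firing rate.
#'
#' @param model A \code{subunit_model} or \code{ln_model}.
#' @param stim A \code{cone_stimulus}.
#' @param seed Optional integer seed (deterministic per seed).
#' @return Length-T integer vector of spike counts.
#' @export
simulate_spikes <- function(model, stim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- predict(model, stim)
  stats::rpois(length(z), z)
}

#' @param object A \code{subunit_model}.
#' @param nsim Number of response repeats to draw.
#' @param seed Optional integer seed.
#' @param stimulus A \code{cone_stimulus}.
#' @param ... Unused.
#' @return For \code{simulate}: an nsim x T integer matrix of spike counts.
#' @rdname simulate_spikes
#' @export
simulate.subunit_model <- function(object, nsim = 1, seed = NULL,
                                   stimulus, ...) {
  if (!is.null(seed)) set.seed(seed)
  z <- firing_rate(object, stimulus)
  matrix(stats::rpois(nsim * length(z), rep(z, each = nsim)), nrow = nsim)
}
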