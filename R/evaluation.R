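# Accuracy metrics and model comparisons: cross-validated R^2,
# reliability-adjusted R^2, maximally differentiating stimuli, improvement
# slopes, grating cycle averages and frequency-doubling indices, paired-cone
# normalization and scoring, and the bootstrap model-comparison test.

#' Fraction of response variance explained
#'
#' \code{R^2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)}. Computed
#' on held-out data this is the cross-validated accuracy; it is at most 1
#' and can be negative when the prediction is worse than the observed mean.
#'
#' @param pred Predicted rate vector.
#' @param obs Observed counts or rates (same length, positive variance).
#' @return A scalar \code{<= 1}.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  ss <- sum((obs - mean(obs))^2)
  if (ss <= 0) stop("observed responses have zero variance")
  1 - sum((pred - obs)^2) / ss
}

#' Select maximally differentiating stimulus frames
#'
#' Returns the indices of the \code{floor(fraction * T)} frames on which the
#' squared difference between two models' predictions is largest. Selection
#' depends only on the predictions, never on the observed responses, so
#' comparing both models on the selected frames favors neither a priori.
#' Ties are broken by ascending frame index.
#'
#' @param pred_a,pred_b Prediction vectors of equal length.
#' @param fraction Fraction of frames to select (default 0.2).
#' @return Sorted integer frame indices.
#' @export
select_max_diff_frames <- function(pred_a, pred_b, fraction = 0.2) {
  if (length(pred_a) != length(pred_b)) stop("prediction lengths differ")
  k <- floor(fraction * length(pred_a))
  if (k < 1) stop("fraction selects no frames")
  d2 <- (pred_a - pred_b)^2
  sort(order(-d2, seq_along(d2))[seq_len(k)])
}

#' Improvement slope between two models across cells
#'
#' The per-retina improvement of model B over model A: the slope of the
#' best-fitting regression line through the origin relating the cells' R^2
#' values, \code{sum(a * b) / sum(a^2)}. When scoring maximally
#' differentiating stimuli, cells whose reference-model R^2 is negative can
#' be excluded (their predictions failed outright on those frames).
#'
#' @param r2_b Per-cell R^2 of the improved model (e.g. subunit).
#' @param r2_a Per-cell R^2 of the reference model (e.g. LN).
#' @param exclude_negative_reference Drop cells with \code{r2_a < 0} before
#'   computing the slope (default FALSE).
#' @return The slope (1 means no improvement, 1.18 means +18 percent).
#' @export
improvement_slope <- function(r2_b, r2_a, exclude_negative_reference = FALSE) {
  if (length(r2_a) != length(r2_b)) stop("R^2 vectors differ in length")
  if (exclude_negative_reference) {
    keep <- r2_a >= 0
    r2_a <- r2_a[keep]; r2_b <- r2_b[keep]
  }
  if (length(r2_a) < 1) stop("no cells left after exclusions")
  sum(r2_a * r2_b) / sum(r2_a^2)
}

#' Reliability-adjusted R-squared from repeated trials
#'
#' Prediction accuracy normalized by response reliability, both measured as
#' squared correlation so an arbitrary offset and gain are allowed. The
#' numerator averages \code{cor(pred, trial)^2} over trials; the denominator
#' averages \code{cor(trial, mean of the remaining trials)^2}; the ratio is
#' the fraction of explainable response variance captured by the model.
#'
#' @param per_trial_counts repeats x T matrix of responses to the identical
#'   stimulus (>= 3 repeats).
#' @param pred Length-T predicted rate.
#' @param components Also return the averaged numerator and denominator
#'   (attributes \code{"num"} and \code{"den"}), so adjusted R^2 values can
#'   be pooled across conditions as a ratio of averages.
#' @return The adjusted R^2 (near 1 for a perfect model of a reliable cell).
#' @export
adjusted_r_squared <- function(per_trial_counts, pred, components = FALSE) {
  m <- as.matrix(per_trial_counts)
  if (nrow(m) < 3) stop("need at least 3 repeats")
  if (ncol(m) != length(pred)) stop("trial length does not match prediction")
  ok <- apply(m, 1, stats::var) > 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-variance trial(s) skipped")
    m <- m[ok, , drop = FALSE]
    if (nrow(m) < 3) stop("fewer than 3 usable repeats")
  }
  if (stats::var(pred) <= 0) stop("prediction has zero variance")
  num <- den <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    others <- colMeans(m[-i, , drop = FALSE])
    num[i] <- stats::cor(pred, m[i, ])^2
    den[i] <- if (stats::var(others) > 0) stats::cor(m[i, ], others)^2 else NA
  }
  out <- mean(num) / mean(den, na.rm = TRUE)
  if (components) {
    attr(out, "num") <- mean(num)
    attr(out, "den") <- mean(den, na.rm = TRUE)
  }
  out
}

#' Cycle-averaged response to a periodic stimulus
#'
#' Folds spike counts over the contrast-modulation cycles of a grating
#' presentation and averages across cycles (and repeats when a matrix is
#' given), giving the mean response over one cycle.
#'
#' @param counts Length-T vector, or repeats x T matrix, of responses to a
#'   periodic stimulus (T a whole number of cycles).
#' @param frame_rate_hz Frame rate.
#' @param temporal_freq_hz Stimulus modulation frequency (default 2 Hz).
#' @return Numeric vector of length frames-per-cycle: the average counts per
#'   frame over one cycle.
#' @export
cycle_average <- function(counts, frame_rate_hz, temporal_freq_hz = 2) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1)
  fpc <- frame_rate_hz / temporal_freq_hz
  if (abs(fpc - round(fpc)) > 1e-8)
    stop("frame rate must be an integer multiple of the modulation frequency")
  fpc <- as.integer(round(fpc))
  if (ncol(m) %% fpc != 0)
    stop("response length is not a whole number of cycles")
  folded <- array(t(m), dim = c(fpc, ncol(m) / fpc * nrow(m)))
  rowMeans(folded)
}

#' Fundamental and second-harmonic response amplitudes
#'
#' Discrete Fourier amplitudes of a cycle-averaged response at the stimulus
#' frequency (F1) and at twice the stimulus frequency (F2). Frequency
#' doubling - F2 exceeding F1 - is the classic signature of rectified
#' subunits responding to a contrast-reversing grating at its null phase.
#'
#' @param cycle_avg Cycle-averaged response ([cycle_average()]).
#' @return Named vector \code{c(F1 = , F2 = )} of amplitudes (same units as
#'   the input).
#' @export
f1_f2_amplitudes <- function(cycle_avg) {
  n <- length(cycle_avg)
  if (n < 5) stop("need at least 5 bins per cycle to resolve F2")
  sp <- stats::fft(cycle_avg)
  c(F1 = 2 * Mod(sp[2]) / n, F2 = 2 * Mod(sp[3]) / n)
}

#' Normalize single/paired cone response tables
#'
#' For each tested cone the experiment yields four firing rates (the single
#' stimulation plus three pairings); each set of four is divided by its
#' maximum, so the largest normalized value is exactly 1. The same
#' normalization is applied to model predictions before scoring.
#'
#' @param rates Numeric vector of 4 rates, or an n x 4 matrix (one row per
#'   tested cone).
#' @return Same shape, rowwise divided by the maximum.
#' @export
paired_response_table <- function(rates) {
  if (is.matrix(rates)) {
    mx <- apply(rates, 1, max)
    if (any(mx <= 0)) stop("each tested cone needs a positive maximum rate")
    sweep(rates, 1, mx, "/")
  } else {
    if (max(rates) <= 0) stop("needs a positive maximum rate")
    rates / max(rates)
  }
}

#' Paired-cone prediction accuracy
#'
#' The squared correlation between measured and predicted normalized
#' responses across all tested cone pairs.
#'
#' @param measured,predicted Aligned numeric vectors or matrices of
#'   normalized responses.
#' @return Scalar in [0, 1].
#' @export
paired_prediction_score <- function(measured, predicted) {
  m <- as.vector(as.matrix(measured))
  p <- as.vector(as.matrix(predicted))
  if (length(m) != length(p)) stop("measured and predicted sizes differ")
  stats::cor(m, p)^2
}

#' Bootstrap comparison of paired-cone prediction accuracy
#'
#' Compares the first model's paired-cone accuracy against each other model.
#' On each bootstrap draw, cone-pair rows are resampled with replacement,
#' every model's accuracy (squared correlation with the measured responses)
#' is re-estimated, and the differences are recorded. A model comparison is
#' significant if the fifth percentile of the difference distribution
#' exceeds zero.
#'
#' @param measured Numeric vector of measured normalized responses, one per
#'   cone-pair row (>= 10 rows).
#' @param predictions Named list (>= 2 models) of prediction vectors aligned
#'   with \code{measured}; the first model is compared against the rest.
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param seed Optional integer seed (deterministic per seed).
#' @return List with \code{accuracies} (full-sample r^2 per model),
#'   \code{deltas} (n_boot x (models - 1) matrix of accuracy differences),
#'   \code{fifth_percentile}, and logical \code{significant} per comparison.
#' @export
bootstrap_model_comparison <- function(measured, predictions, n_boot = 10000,
                                       seed = NULL) {
  if (length(predictions) < 2) stop("need at least 2 models to compare")
  if (is.null(names(predictions)))
    names(predictions) <- paste0("model", seq_along(predictions))
  n <- length(measured)
  if (n < 10) stop("need at least 10 cone pairs")
  for (p in predictions)
    if (length(p) != n) stop("prediction length does not match measured")
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(predictions, function(p) stats::cor(measured, p)^2, 0)
  others <- names(predictions)[-1]
  deltas <- matrix(NA_real_, n_boot, length(others),
                   dimnames = list(NULL, others))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::var(measured[idx]) <= 0) next
    a <- vapply(predictions, function(p) {
      if (stats::var(p[idx]) <= 0) return(NA_real_)
      stats::cor(measured[idx], p[idx])^2
    }, 0)
    deltas[b, ] <- a[1] - a[-1]
  }
  q5 <- apply(deltas, 2, stats::quantile, probs = 0.05, na.rm = TRUE)
  list(accuracies = acc, deltas = deltas, fifth_percentile = q5,
       significant = q5 > 0)
}

#' Held-out accuracy report for a set of fitted models
#'
#' Scores several models fit to the same data (same split) on the held-out
#' frames: overall test R^2, and R^2 restricted to the maximally
#' differentiating frames between the first two models. A model whose
#' max-diff R^2 is negative is flagged; such cells are excluded from
#' improvement-slope summaries over populations
#' (see [improvement_slope()]).
#'
#' @param fits Named list of \code{subunit_fit} / \code{ln_fit} objects
#'   sharing the same data and train/test split (fit with
#'   \code{keep_data = TRUE}).
#' @param fraction Fraction of held-out frames kept in the max-diff subset.
#' @return Data frame with one row per model: \code{model}, \code{r2_test},
#'   \code{r2_maxdiff}, \code{excluded_maxdiff}.
#' @export
metric_report <- function(fits, fraction = 0.2) {
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ref <- fits[[1]]
  if (is.null(ref$stimulus))
    stop("fits must carry their data (keep_data = TRUE)")
  for (f in fits[-1])
    if (!identical(f$test, ref$test))
      stop("all fits must share the same train/test split")
  stim <- stim_subset(ref$stimulus, ref$test)
  obs <- ref$counts[ref$test]
  preds <- lapply(fits, function(f) predict(f, stim))
  r2 <- vapply(preds, r_squared, 0, obs = obs)
  if (length(fits) >= 2) {
    sel <- select_max_diff_frames(preds[[1]], preds[[2]], fraction)
    md <- vapply(preds, function(p) r_squared(p[sel], obs[sel]), 0)
  } else md <- NA_real_
  data.frame(model = names(fits), r2_test = unname(r2),
             r2_maxdiff = unname(md),
             excluded_maxdiff = unname(md < 0))
}

#' Cancellation index for paired opposite-polarity stimulation
#'
#' The ratio of the response to paired opposite-polarity stimulation to the
#' response to the single-cone decrement alone. A ratio of at least 0.5
#' (failure of cancellation) indicates the two cones drive distinct
#' subunits; strong cancellation indicates they share one.
#'
#' @param single_rate Response to the single-cone decrement (> 0).
#' @param paired_rate Response to the paired increment/decrement.
#' @return List with \code{ratio} and logical \code{non_cancelling}
#'   (\code{ratio >= 0.5}).
#' @export
cancellation_index <- function(single_rate, paired_rate) {
  if (single_rate <= 0) stop("single-cone response must be positive")
  ratio <- paired_rate / single_rate
  list(ratio = ratio, non_cancelling = ratio >= 0.5)
}

#' Null spatial phase of a linear receptive field
#'
#' The grating phase at which the net linear drive of a weighted cone sum is
#' zero: with per-cone drive \code{w_c * att_c * sin(2 pi x_c / period +
#' phase)}, the summed drive is a single sinusoid in phase, and its zero
#' crossing is returned (in [0, 2 pi)).
#'
#' @param weights Per-cone linear weights.
#' @param mosaic A [make_mosaic()] table (same cone order).
#' @param period Grating spatial period (microns).
#' @return The null phase in radians.
#' @export
null_phase <- function(weights, mosaic, period) {
  att <- grating_attenuation(mosaic$sigma, period) * mosaic$gain
  theta <- 2 * pi * mosaic$x / period
  P <- sum(weights * att * sin(theta))
  Q <- sum(weights * att * cos(theta))
  atan2(-P, Q) %% (2 * pi)
}
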