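# Experiment drivers for the two qualitative validations of recovered
# subunit structure: frequency doubling under contrast-reversing gratings,
# and closed-loop single/paired cone increment-decrement stimulation.

#' Grating validation experiment
#'
#' Presents contrast-reversing gratings (a grid of spatial periods and
#' phases) to a ground-truth model, simulates Poisson responses, and scores
#' each candidate model's predictions: the F1/F2 amplitudes of the predicted
#' cycle average (frequency doubling shows up as F2 > F1), and the
#' reliability-adjusted R-squared of the prediction against the per-cycle
#' simulated responses (each modulation cycle of each presentation is one
#' trial, and each trial's reference is the average over the remaining
#' trials).
#'
#' @param models Named list of fitted models (\code{subunit_model} or
#'   \code{ln_model}) to score.
#' @param truth Ground-truth \code{subunit_model} generating the responses.
#' @param mosaic Cone mosaic ([make_mosaic()]) shared by truth and models.
#' @param periods Spatial periods (microns) to test.
#' @param n_phases Number of evenly spaced spatial phases (default 8).
#' @param frame_rate_hz Frame rate (default 12).
#' @param temporal_freq_hz Contrast modulation frequency (default 2 Hz).
#' @param contrast Grating contrast.
#' @param duration_s Presentation length (default 8 s; gaps are omitted from
#'   the analysis).
#' @param repeats Presentations per condition (default 3).
#' @param seed Integer seed for the simulated responses.
#' @return Data frame with one row per (model, period, phase): predicted
#'   \code{F1}, \code{F2}, measured \code{F1_obs}, \code{F2_obs},
#'   \code{adjusted_r2} (0 when the prediction carries no modulation), and
#'   its trial-averaged components \code{adjr2_num} / \code{adjr2_den}.
#'   Period-level adjusted R^2 is the ratio of the components summed over
#'   the period's phases (the ratio of trial-averaged correlations), which
#'   is stabler than averaging the per-phase ratios.
#' @export
run_grating_validation <- function(models, truth, mosaic, periods,
                                   n_phases = 8, frame_rate_hz = 12,
                                   temporal_freq_hz = 2, contrast = 0.96,
                                   duration_s = 8, repeats = 3, seed = 1) {
  if (is.null(names(models))) stop("models must be a named list")
  phases <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  fpc <- as.integer(round(frame_rate_hz / temporal_freq_hz))
  rows <- list(); k <- 0L
  for (pi_ in seq_along(periods)) {
    for (ph in seq_len(n_phases)) {
      spec <- grating_spec(periods[pi_], phases[ph],
                           temporal_freq_hz = temporal_freq_hz,
                           contrast = contrast, duration_s = duration_s,
                           gap_s = 0, repeats = repeats)
      stim <- grating_cone_inputs(mosaic, spec, frame_rate_hz)
      counts <- simulate_spikes(truth, stim,
                                seed = seed + 131L * pi_ + 7L * ph)
      trials <- matrix(counts, ncol = fpc, byrow = TRUE)
      obs_prof <- cycle_average(counts, frame_rate_hz, temporal_freq_hz)
      obs_amp <- f1_f2_amplitudes(obs_prof)
      for (m in names(models)) {
        pred <- predict(models[[m]], stim)
        prof <- cycle_average(pred, frame_rate_hz, temporal_freq_hz)
        amp <- f1_f2_amplitudes(prof)
        if (stats::var(prof) <= 1e-20) {
          ar2 <- 0; a_num <- 0; a_den <- NA_real_
        } else {
          ar2 <- suppressWarnings(adjusted_r_squared(trials, prof,
                                                     components = TRUE))
          a_num <- attr(ar2, "num"); a_den <- attr(ar2, "den")
          ar2 <- as.numeric(ar2)
        }
        k <- k + 1L
        rows[[k]] <- data.frame(model = m, period = periods[pi_],
                                phase = phases[ph], F1 = amp[["F1"]],
                                F2 = amp[["F2"]], F1_obs = obs_amp[["F1"]],
                                F2_obs = obs_amp[["F2"]],
                                adjusted_r2 = ar2, adjr2_num = a_num,
                                adjr2_den = a_den)
      }
    }
  }
  do.call(rbind, rows)
}

#' Period-level adjusted R-squared from a grating validation table
#'
#' Pools all trials of a spatial period (every phase) and returns the ratio
#' of the trial-averaged prediction correlation to the trial-averaged
#' reliability correlation, per model and period.
#'
#' @param results Output of [run_grating_validation()].
#' @return Data frame with columns \code{model}, \code{period},
#'   \code{adjusted_r2}.
#' @export
grating_period_adjusted_r2 <- function(results) {
  agg_num <- stats::aggregate(adjr2_num ~ model + period, data = results,
                              FUN = mean)
  agg_den <- stats::aggregate(adjr2_den ~ model + period, data = results,
                              FUN = mean, na.action = stats::na.omit)
  out <- merge(agg_num, agg_den)
  out$adjusted_r2 <- out$adjr2_num / out$adjr2_den
  out[order(out$model, out$period), c("model", "period", "adjusted_r2")]
}

# mean firing rate (spikes/frame) in the response window of each trial,
# averaged over trials; frames whose start falls inside the window count
window_rate <- function(values_by_frame, onsets, frames_per_trial,
                        frame_rate_hz, window_s = 0.3) {
  in_win <- ((seq_len(frames_per_trial) - 1) / frame_rate_hz) < window_s
  rates <- vapply(onsets, function(o)
    mean(values_by_frame[o + which(in_win) - 1L]), 0)
  mean(rates)
}

#' Closed-loop paired-cone validation experiment
#'
#' Emulates the closed-loop increment-decrement experiment: for each
#' ground-truth cell, models are fit to temporally aligned white-noise
#' responses; a set of tested cones then each receives a decrement alone and
#' paired with an increment to several partner cones. Measured responses are
#' simulated Poisson trials from the truth, averaged over repeats within a
#' 300 ms window and normalized by each tested cone's maximum; model
#' predictions are normalized the same way. Accuracy is the squared
#' correlation between measured and predicted normalized responses across
#' all pairings.
#'
#' @param cell_truths List of ground-truth \code{subunit_model}s (one per
#'   cell).
#' @param duration_min White-noise fitting duration per cell (minutes).
#' @param n_test_cones Tested cones per cell (default 4).
#' @param n_pairings Partner cones per tested cone (default 3).
#' @param repeats Trials per condition (default 20).
#' @param window_s Response window from stimulus onset (default 0.3 s).
#' @param frame_rate_hz Frame rate.
#' @param contrast Stimulus contrast for noise and spots.
#' @param config [fit_config()] for the fits.
#' @param temporal_kernel Kernel for [sta_temporal_align()] applied to the
#'   fitting noise (\code{NULL} for raw binary inputs).
#' @param seed Integer master seed.
#' @return List of class \code{"paired_cone_validation"}: \code{table} (one
#'   row per tested pairing: cell, tested cone, partner, whether the pair
#'   shares a true subunit, measured and per-model predicted normalized
#'   responses), \code{scores} (r^2 per model), and \code{n_pairs}.
#' @export
run_paired_cone_validation <- function(cell_truths, duration_min = 8,
                                       n_test_cones = 4, n_pairings = 3,
                                       repeats = 20, window_s = 0.3,
                                       frame_rate_hz = 12, contrast = 0.96,
                                       config = fit_config(),
                                       temporal_kernel = sta_kernel(frame_rate_hz),
                                       seed = 1) {
  rows <- list(); k <- 0L
  for (cell in seq_along(cell_truths)) {
    truth <- cell_truths[[cell]]
    C <- ncol(truth$indicator)
    base <- as.integer(seed) + 7919L * cell
    mosaic <- make_mosaic(C, seed = base)
    noise <- white_noise_cone_stimulus(C, duration_min, frame_rate_hz,
                                       contrast, seed = base + 1L)
    if (!is.null(temporal_kernel))
      noise <- sta_temporal_align(noise, temporal_kernel)
    counts <- simulate_spikes(truth, noise, seed = base + 2L)
    cfg <- config; cfg$seed <- base + 3L; cfg$keep_data <- FALSE
    fits <- list(
      subunit = fit_subunit_model(noise, counts, cfg)$model,
      single_cone = fit_single_cone_model(noise, counts, cfg)$model,
      ln = fit_ln_model(noise, counts, cfg)$model)
    # closed-loop targeting from the FITTED subunit model: tested cones are
    # the strongest cone of each fitted multi-cone subunit, then remaining
    # cones by fitted effective weight; partners are the cone's fitted
    # within-subunit mates first, then the strongest remaining cones
    fitm <- fits$subunit
    eff <- abs(drop(crossprod(pooling_matrix(fitm), fitm$subunit_weights)))
    sub_fit <- apply(fitm$indicator, 2, which.max)
    multi <- which(rowSums(fitm$indicator) > 1)
    lead <- vapply(multi, function(s) {
      cs <- which(fitm$indicator[s, ] == 1)
      cs[which.max(eff[cs])]
    }, 0L)
    lead <- lead[order(-eff[lead])]
    tested <- c(lead, setdiff(order(-eff), lead))[seq_len(min(n_test_cones, C))]
    subunit_of <- apply(truth$indicator, 2, which.max)
    for (cone in tested) {
      mates <- setdiff(which(fitm$indicator[sub_fit[cone], ] == 1), cone)
      mates <- mates[order(-eff[mates])]
      others <- setdiff(order(-eff), c(cone, mates))
      partners <- c(mates, others)[seq_len(min(n_pairings, C - 1))]
      conds <- c(list(single = list(ids = cone, pol = -1)),
                 stats::setNames(lapply(partners, function(p)
                   list(ids = c(cone, p), pol = c(-1, 1))),
                   paste0("pair", partners)))
      measured <- numeric(length(conds))
      preds <- matrix(0, length(conds), length(fits),
                      dimnames = list(NULL, names(fits)))
      for (ci in seq_along(conds)) {
        spec <- targeted_trial_spec(mosaic$id[conds[[ci]]$ids],
                                    conds[[ci]]$pol, contrast = contrast,
                                    repeats = repeats)
        trial <- targeted_cone_inputs(mosaic, spec, frame_rate_hz)
        sim <- simulate_spikes(truth, trial$stimulus,
                               seed = base + 101L * cone + 11L * ci)
        measured[ci] <- window_rate(sim, trial$onsets,
                                    trial$frames_per_trial, frame_rate_hz,
                                    window_s)
        for (m in names(fits))
          preds[ci, m] <- window_rate(predict(fits[[m]], trial$stimulus),
                                      trial$onsets, trial$frames_per_trial,
                                      frame_rate_hz, window_s)
      }
      if (max(measured) <= 0) next  # cone never drove a spike in any condition
      measured_n <- paired_response_table(measured)
      preds_n <- apply(preds, 2, paired_response_table)
      for (ci in seq_along(conds)[-1]) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          cell = cell, cone = cone, partner = partners[ci - 1L],
          within_subunit = subunit_of[cone] == subunit_of[partners[ci - 1L]],
          measured = measured_n[ci],
          pred_subunit = preds_n[ci, "subunit"],
          pred_single_cone = preds_n[ci, "single_cone"],
          pred_ln = preds_n[ci, "ln"])
      }
    }
  }
  table <- do.call(rbind, rows)
  scores <- c(subunit = paired_prediction_score(table$measured,
                                                table$pred_subunit),
              single_cone = paired_prediction_score(table$measured,
                                                    table$pred_single_cone),
              ln = paired_prediction_score(table$measured, table$pred_ln))
  structure(list(table = table, scores = scores, n_pairs = nrow(table)),
            class = "paired_cone_validation")
}

#' @export
print.paired_cone_validation <- function(x, ...) {
  cat("Closed-loop paired-cone validation:", x$n_pairs, "pairings from",
      length(unique(x$table$cell)), "cells\n")
  cat("  prediction r^2:\n")
  print(round(x$scores, 3))
  invisible(x)
}
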