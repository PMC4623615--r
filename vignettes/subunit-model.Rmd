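---
title: "Inferring nonlinear subunits in retinal ganglion cell receptive fields"
author: "rgcsubunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nonlinear subunits in retinal ganglion cell receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcsubunits)
```

## The model

Retinal ganglion cells (RGCs) do not pool their cone photoreceptor inputs
linearly. Cone signals first converge onto bipolar cells, whose output is
rectified at the synapse onto the RGC; the bipolar cells are the anatomical
correlate of nonlinear receptive-field *subunits*. This package implements a
hierarchical cascade that makes that circuit explicit at single-cone
resolution — a linear–nonlinear–linear–nonlinear–Poisson (LNLN-P) model:

* Cone inputs $x_{ct}$ (a $C \times T$ matrix of contrast values, one row
  per cone, one column per stimulus frame) are pooled within non-overlapping
  subunits. The pooling matrix is $U = I \odot A$, where $I$ is a binary
  assignment matrix (each cone belongs to exactly one subunit) and $A$ holds
  the positive within-subunit weights, normalized to sum to 1 per subunit.
* Each subunit's pooled drive passes through a shared nonlinearity $f$:
  $y_{st} = f\!\left(\sum_c u_{sc} x_{ct}\right)$.
* Subunit outputs are weighted by an unconstrained vector $w$ and summed,
  and the output nonlinearity $g$ converts the net drive to a firing rate
  (spikes/frame): $z_t = g\!\left(\sum_s w_s y_{st}\right)$.
* Spike counts $r_t$ are conditionally Poisson with rate $z_t$, giving the
  log-likelihood $\sum_t r_t \log z_t - \sum_t z_t$ (the count-factorial
  constant is omitted; it cancels in every model comparison).

Setting $I = A = \mathrm{identity}$ and $f$ linear collapses the cascade to
the classic LN model (`ln_model()`, `fit_ln_model()`); keeping $I =
\mathrm{identity}$ but $f$ free gives the *single-cone subunit model*
(`fit_single_cone_model()`). Both reductions serve as baselines.

### Nonlinearities

$f$ and $g$ are cubic splines with eight node points, constrained to have
continuous first and second derivatives. We parameterize each by its eight
nodal values and take the natural cubic interpolant: the constraint set is
then satisfied by construction, evaluation is linear in the parameters
(`spline_basis()`), and the curve continues linearly beyond the end nodes —
a deliberate choice that keeps extrapolated drives from exploding. Nodes are
placed uniformly between the 1st and 99th percentiles of the current drive
distribution at the time of each sub-fit, so the spline's flexibility is
spent where the data are.

$f$ is initialized as negative half-wave rectification $\min(v, 0)$ and $g$
as the softplus $\log(1 + e^v)$. Note the conventions that make the model
identifiable only up to harmless symmetries: the sign of $f$ trades off
against the sign of $w$ (an OFF cell can be fit with a negative-going $f$
and positive weights or vice versa), and a gain on $f$ trades off against
$1/w$. The row normalization of $A$ pins the within-subunit scale; nothing
pins the $f$-versus-$w$ gain, which is why recovered nonlinearities are
compared after normalizing out gain, offset and sign.

## Fitting

`fit_subunit_model()` decomposes the estimation into:

1. **Coordinate ascent over the continuous parameters** for a fixed
   assignment (`fit_continuous()`): repeated rounds of a $w$-step, an
   $A$-step and an $f$-step, each maximizing the training Poisson
   log-likelihood with the other blocks fixed (BFGS with analytic
   gradients; the $A$-step works through a softmax reparameterization that
   enforces positivity and row sums of 1). Every sub-step keeps the better
   of its start and its optimum, so the likelihood trace is non-decreasing
   by construction. The loop stops when the relative likelihood change in a
   round falls below `rel_tol` (default 1e-6) or after `max_rounds`
   (default 20). The output nonlinearity $g$ is refit **once at the end**;
   it stays at its softplus initialization throughout the search so that
   all assignment comparisons happen under a common $g$.
2. **Greedy agglomerative search over assignments**: starting from the
   identity ("single-cone") assignment, every possible pairing of two
   subunits is evaluated by refitting the continuous parameters,
   warm-started from the current fit with a reduced budget
   (`candidate_rounds`, default 5, with early exit at `candidate_rel_tol`).
   The best pair is merged if and only if it improves the maximized
   training likelihood; otherwise the search stops. At most $C - 1$ merges
   can occur. Before each round the unmerged model receives the same
   incremental budget the candidates get, so the accept/reject comparison
   is not biased by one side having had more ascent iterations. An accepted
   merge is re-estimated to full tolerance both by continuing the
   warm-started candidate and from a fresh initialization ($w$, $A$ all
   ones, $f$ rectifying, $g$ softplus); the better of the two is kept. The
   fresh restart guards against local optima inherited through the
   warm-started path, which we observed to otherwise distort merge
   decisions. The merged pair's warm start concatenates the two subunits'
   cone weights scaled by $|w_s|$ (renormalized), and sums the two subunit
   weights. Ties among equal-improvement merges resolve to the lowest index
   pair.

Fits use the training portion of a blocked train/test split
(`split_train_test()`): held-out frames form contiguous blocks of roughly
one minute placed randomly within equal segments of the recording, so test
data are distributed across the experiment's duration (robust to slow
nonstationarities) rather than being i.i.d. frames. All randomness — the
split and any simulation — flows from the integer seed in `fit_config()`,
making a fit fully reproducible.

Degenerate inputs are handled explicitly: a zero-variance stimulus leaves
the $A$-step unidentifiable, so it returns its initialization and sets a
flag in the fit; all rates are floored at `rate_floor` (default $10^{-6}$
spikes/frame) before the log so the likelihood is always defined; an
optimizer that fails to improve a block simply leaves it unchanged.

## The synthetic retina

Everything needed to exercise the pipeline is generated in code:

* `make_mosaic()` draws a jittered-lattice cone mosaic (default spacing
  10 µm, Gaussian aperture σ = 3 µm, typical of peripheral primate retina).
* `white_noise_cone_stimulus()` produces i.i.d. binary ±0.96-contrast cone
  inputs at 12 Hz (83 ms bins), the standard fitting ensemble.
* `sta_temporal_align()` convolves cone inputs with a biphasic temporal
  kernel (`sta_kernel()`), reproducing the preprocessing step in which cone
  signals are filtered by the temporal component of the spike-triggered
  average before a purely spatial model is fit. This step matters more than
  it may look: under strictly binary frame-resolution inputs, the drive of
  a merged, equally weighted pair of single-cone subunits takes only three
  or four distinct values, at which a free shared $f$ can exactly imitate
  two independently rectified cones — the partition over singleton subunits
  is then *unidentifiable*, and greedy merging over-merges. Temporally
  filtered inputs are continuous, break that equivalence, and are what the
  model ingests in a real experiment. The recovery and validation
  experiments therefore fit to aligned inputs.
* `grating_cone_inputs()` projects contrast-reversing sinusoidal gratings
  (default 2 Hz modulation, 8 s on, 2 s gap, 3 repeats) through each cone's
  Gaussian aperture in closed form — attenuation
  $\exp(-2\pi^2\sigma^2/\lambda^2)$, verified against numerical quadrature
  in the tests. The temporal waveform is sinusoidal by default (square-wave
  reversal available), a choice left open by the physiology.
* `targeted_cone_inputs()` builds closed-loop single/paired-cone trials:
  750 ms trials with a 250 ms stimulus window, spots of radius 8.5 µm (the
  midpoint of the 7.65–9.35 µm range used experimentally) whose coupling to
  a cone is the analytic Gaussian-disk overlap
  $1 - \exp(-R^2/2\sigma^2)$.
* `repeated_noise_block()` repeats one noise sequence (default 10 s; the
  length is a parameter since reported protocols used both 8 and 10 s)
  with independent Poisson draws per repeat.
* `example_ground_truth()` is the canonical simulated cell: non-overlapping
  subunits (default eight cones in subunits of sizes 2, 2, 1, 1, 1, 1),
  mildly asymmetric within-subunit weights, OFF-polarity subunit weights
  near −1, a rectifying $f$ with a node at zero (so a silent subunit
  contributes exactly zero drive), and a soft-threshold $g$ whose threshold
  scales with the number of subunits so mean rates stay near 10–20 spikes/s
  under full-contrast noise regardless of configuration. The `g_gain`
  parameter (default 1.6) controls the threshold's sharpness; the
  closed-loop experiments use `g_gain = 3`, emulating the low-baseline,
  strongly responding cells that are deliberately selected for targeted
  stimulation.

What the generator does *not* emulate: temporal response dynamics (the
model is memoryless, so responses end with the stimulus frame), receptive
field surrounds, adaptation and gain control, spike-history effects, cone
noise, and eye/tissue movement. Passing tests therefore demonstrate that
the estimator recovers the structure it assumes, under Poisson noise at
realistic rates and durations — not that the model family suffices for an
arbitrary real recording.

## Evaluation metrics

* `r_squared()` — fraction of response variance explained,
  $1 - \sum(z_t - r_t)^2 / \sum(r_t - \bar r)^2$, computed on held-out
  frames.
* `select_max_diff_frames()` — the 20% of held-out frames (⌊0.2 T⌋, ties by
  ascending index) where two models' predictions differ most, chosen from
  predictions only; permuting the observed counts cannot change the
  selection, so comparisons on these frames favor neither model a priori.
* `improvement_slope()` — per-retina improvement of one model over another:
  the slope of the best-fitting regression line through the origin relating
  per-cell $R^2$ values; cells with negative reference-model $R^2$ can be
  excluded (used only for the maximally differentiating analysis).
* `adjusted_r_squared()` — accuracy relative to trial-to-trial reliability
  from repeated stimuli: mean over trials of $\mathrm{corr}^2$(prediction,
  trial) divided by mean over trials of $\mathrm{corr}^2$(trial, mean of
  remaining trials). Being correlation-based it allows an arbitrary gain
  and offset. Note this ratio estimator can legitimately exceed 1 when the
  prediction is close to the true rate: the numerator correlates a
  noiseless curve with a noisy trial while the denominator correlates two
  noisy quantities. It converges to 1 from either side as repeats grow.
* `cycle_average()` and `f1_f2_amplitudes()` — fold responses over grating
  modulation cycles and extract the first two Fourier amplitudes; a second
  harmonic exceeding the fundamental (F2 > F1) is the classic frequency-
  doubling signature of rectified subunits, sharpest at the null phase
  (`null_phase()`), where the linear drive cancels exactly.
* `paired_response_table()`, `paired_prediction_score()`,
  `bootstrap_model_comparison()` — the closed-loop scoring pipeline: the
  four rates per tested cone (single stimulation plus three pairings,
  averaged over repeats in a 300 ms window) are divided by their maximum,
  predictions are normalized identically, accuracy is the squared
  correlation across all pairings, and models are compared by resampling
  cone-pair rows with replacement (10,000 draws by default; a comparison is
  significant when the 5th percentile of the accuracy difference exceeds
  zero).
* `cancellation_index()` — the paired/single response ratio with the 0.5
  threshold separating cancelling (shared subunit) from non-cancelling
  (separate subunits) cone pairs.

## The validation experiments

`run_recovery()` replays the estimator-validation design: simulate from the
canonical ground truth at 4, 8 and 16 minutes (12 Hz), five replicates
each, refit from scratch, and score exact partition recovery, cone-weight
RMS error, and the RMS error of $f$ over its central node range (after
normalizing out gain, offset and sign). When the fitted partition differs
from the truth, weights and nonlinearities are scored after refitting the
continuous parameters under the true assignment, since the comparison is
otherwise undefined.

`run_grating_validation()` fits subunit and LN models to 30 minutes of
aligned noise from a rectifying two-subunit cell, then scores grating
predictions over five spatial periods (12–80 µm against 10 µm cone spacing)
and eight phases: per-cycle adjusted $R^2$ (each modulation cycle of each
presentation is a trial) and predicted F1/F2. The expected pattern — and
what the test suite asserts — is F2 > F1 for the subunit prediction
at the null phase of a high-frequency grating, essentially no second
harmonic for the LN prediction, and higher adjusted $R^2$ for the subunit
model at every period. Period-level adjusted $R^2$ pools all of a period's
trials before taking the ratio (`grating_period_adjusted_r2()`), the
stabler form of the trial-averaged definition. One caveat is inherent to
the geometry: at the finest period tested (12 µm against 10 µm cone
spacing), aperture attenuation combined with within-subunit spatial-phase
cancellation leaves this cell's modulation near the Poisson noise floor, so
both models score at the reliability chance level there and their
difference carries no statistical power — the informative comparisons are
the periods with resolvable responses.

`run_paired_cone_validation()` emulates the closed loop end to end for five
simulated cells: fit all three models to 8 minutes of noise, pick tested
cones and partners from the *fitted* subunit partition (as a closed-loop
experiment would), simulate 40 trials per condition, and score the
normalized response tables. Sixty pairings give the bootstrap comparison
enough rows to separate the full subunit model from both reductions.

Problem sizes throughout (8 cones for recovery, 4–6 for the validation
experiments, 2–30 minute stimuli) were chosen as the smallest that exercise
the phenomena at realistic firing rates; the full recovery experiment runs
in about eight minutes on one core.

## Numerical choices and known limitations

* Rates are floored at $10^{-6}$ spikes/frame; likelihood tolerances are
  1e-6 (relative, convergence) and 1e-9 (monotonicity assertions).
* BFGS iteration caps: 50 per sub-step for full fits, 15 inside candidate
  refits. Candidate refits are warm-started; only accepted merges are refit
  to full tolerance. This makes the $O(S^2)$ merge evaluations cheap at the
  cost of slightly noisy candidate likelihoods near ties.
* The greedy search can in principle stop early (no split or swap moves
  exist), and merge decisions near likelihood-neutral configurations (e.g.
  data simulated from a pure LN cell) are effectively coin flips around a
  small positive bias from extra flexibility — the recovery experiment is
  the guard that this does not happen at experiment-scale signal-to-noise.
* Serialization: models round-trip through JSON (assignment as cone-index
  lists, spline nodes and coefficients, 17 significant digits); stimulus
  and spike data through CSV with a commented metadata header; mosaics
  through plain CSV. `simulate_dataset()` writes a seed-stamped manifest
  sufficient to regenerate every file bit-identically.
* The package deliberately omits: spike history and refractoriness, gain
  control, surrounds, temporal nonlinearities, overlapping subunits, and
  any spatial-adjacency restriction on merges. These are the model's
  scientific assumptions, not implementation shortcuts.
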