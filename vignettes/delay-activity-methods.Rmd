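---
title: "Methods: structure and variability of preparatory neural states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure and variability of preparatory neural states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaystate)
```

## The scientific setting

In an instructed-delay center-out reaching task, a target appears and a
go cue follows several hundred milliseconds later. During that delay the
motor system prepares the reach, and multielectrode recordings from
dorsal premotor cortex show that the population firing-rate vector
settles into a reach-specific "initial condition". This package asks
three questions of such delay activity, using a synthetic stand-in for
the recordings:

1. **Structure** — do the preparatory states organize along
   interpretable axes (reach endpoint x/y and maximum reach speed)?
2. **Variability** — how does the state wander from trial to trial
   around its per-target mean, radially (distance) versus tangentially
   (direction)?
3. **Decodability** — how well can the cued endpoint be classified from
   a single trial, and what is the right geometry (angle, arc-length,
   distance) for reporting the errors?

## The model fit

The data model is a trial table: one row per trial with the per-channel
multiunit rate averaged over the 200 ms before the go cue (spikes/s),
plus task metadata. `delay_subspace()` fits, in order:

1. **Condition averaging.** Trials are averaged within each condition (a
   unique target, pooled over sessions and tasks), giving
   `N_cond` (channels x conditions). Averaging first makes the PCA
   reflect between-condition structure rather than single-trial noise.
2. **PCA.** `N_cond` is mean-centered across conditions and decomposed;
   the smallest number `d` of components whose cumulative explained
   variance reaches the threshold (default 0.95) is retained, giving the
   transform `A` (d x channels).
3. **Spatial plane.** Single-trial PC scores `A(r - center)` are
   regressed (ordinary least squares, no intercept — centering plays
   that role) onto the target's x coordinate, giving the axis
   `x_neural`; the scores are then projected into the null-space of that
   axis and regressed onto y, giving `y_neural`.
4. **Speed axis.** Maximum reach speed is regressed from the
   *full-dimensional* channel-space rates (projected into the null-space
   of the plane), not from the PC scores: the PCs were built from
   condition averages, which average away within-condition speed
   variability, so the speed signal need not survive the reduction.

Because each fit happens in the null-space of the previous axes, the
three channel-space axis vectors are exactly pairwise orthogonal, and a
trial's coordinates `(x_neural, y_neural, speed_neural)` are just inner
products of its centered rate vector with the axes. The regression makes
the coordinates come out in the regressand's units: cm in the plane,
cm/s (relative to the mean) on the speed axis.

Methods on the fitted object: `print`, `summary` (per-task plane
explained variance), `coef` (the axis matrix), `predict` (projects new
trials, or the stored condition averages), `plot`.

### Exact identifiability and its limits

With all generator noise at zero the fit recovers target coordinates
exactly **provided** the encoding loadings are orthogonal across the
three latent variables and the rate floor at 0 spikes/s is never hit.
Both caveats are real properties of the method, not implementation
artifacts: when encoding columns are correlated, projecting the data
into the null-space of the x axis removes a component that the y
regression can no longer compensate (a small, provable leakage — with
96 random channels the column correlations are O(1/sqrt(96)), so the
leakage is a percent-level effect, which is also why the original
sequential procedure barely changed the unorthogonalized projections);
and clipping is a nonlinearity outside the linear model. The noiseless
checks in the test suite therefore use a Gram-Schmidt-orthogonalized
encoding matrix and a baseline (50 spikes/s) that keeps every rate
positive.

### Calibrated single-trial inference

Two analyses regress a behavioral variable on ~96 channels of
single-trial activity and then test properties of the fitted
projection. Done in-sample this is anti-conservative: with k trials and
n channels an ordinary least-squares readout fits noise with in-sample
R^2 ~ n/k, so "speed encoding" would be detected even from channels
containing none. Both are therefore cross-fitted on deterministic
alternating halves:

* `within_distance_speed_test()` re-fits the speed axis on one half
  (in the plane's null-space) and projects the other, so the
  per-distance slope tests are calibrated — with the speed encoding
  removed from the generator, the number of significant distances is
  binomially consistent with the nominal level.
* `residual_distance_correlation()` estimates the per-channel
  speed-residualization *and* the residual distance readout on the
  training half only. Residualizing on the pooled table would constrain
  the pooled readout to be exactly orthogonal to speed, which transmits
  a spurious negative correlation with distance into the held-out half
  (distance and speed being strongly correlated); estimating the
  residualization within the fold removes the artifact.

## Trial-to-trial variability

Deviations are displacements of a trial's in-plane state from its
condition mean, decomposed into an **on-axis** component (projection on
the unit vector from the origin to the condition-mean state; variation
in distance) and an **off-axis** component (projection on its 90
degree rotation; variation in direction). The radial reference is the
mean *neural state* direction, not the instructed target direction
(the option exists), matching how the per-condition ellipses are
oriented. By construction on^2 + off^2 equals the squared in-plane
deviation.

* `welch_ttest()` compares |on| vs |off| (two-sided, unequal
  variances, Welch-Satterthwaite df).
* `equal_frequency_ellipses()` summarizes each condition by its local
  2-D principal axes; one global scale factor is found by bisection so
  the across-condition *average* fraction of trials inside their
  ellipse equals the requested coverage (0.95). A single global scale
  matches the "on average 95%" convention; per-condition quantiles
  would trivially pin every condition at 95%.
* `relative_deviation_profile()` reports mean |on|/d and |off|/d per
  target distance d with SEMs, and a Spearman rank correlation of the
  per-distance means against distance as the monotonicity summary.
* `correlate_neural_kinematic()` applies the identical decomposition to
  the hand position at maximum speed (an early, largely feedforward
  kinematic marker) and correlates neural and kinematic deviations
  componentwise across trials.

## Endpoint decoding

`crossval_classify()` wraps a support-vector classifier (RBF kernel,
one-vs-one voting, cost 1) in stratified 10-fold cross-validation;
folds are stratified because class-imbalanced folds would corrupt
per-ring metrics. The kernel bandwidth is the variance-scaled heuristic
`gamma = 1/(p * var(X))`. Ties in the one-vs-one vote are resolved by
the underlying library's decision values. Error geometry
(`decode_errors()`): angle errors are minimal circular differences in
[0, pi]; arc-length errors multiply by the true ring radius, making
direction errors commensurable with distance errors (cm); distance
errors are |true - predicted| target distance, computed per line
direction (the classifier is trained and tested on one side of the
line at a time and the results aggregated, so direction never leaks
into the distance classifier). Restricted arc means keep only errors
within the half-circumference of the smallest ring — the range of
errors every ring can express — and the same restriction is applied
when comparing arc-error distributions across rings, since the outer
rings can express errors the inner ring cannot.

`ablate_to_plane()` projects trials to `(x_neural, y_neural)` only.
Comparing distance classification with full rates versus plane-only
features isolates the contribution of the speed axis: when the
generator couples speed to distance (slope b > 0), ablation reliably
worsens distance decoding; with b = 0 ablation causes no increase —
in fact the clean 2-D features hold a hair's-breadth (~0.01 cm)
denoising advantage over 96 raw channels, which is why the "no change"
check is a one-sided no-increase test with a magnitude bound rather
than a two-sided equality.

## The synthetic generator

No recordings ship with the package; `simulate_trials()` generates
tables with the statistical structure the analysis assumes (see
`?generator_params`): linear rate encoding of planned endpoint and
speed with Gaussian channel noise (rates are binned multiunit
averages, so Gaussian-on-rates rather than Poisson-on-counts is the
appropriate noise family; clipping at 0 affects well under 1% of
entries at the defaults), a linear speed-distance relation `s = a +
b d + eps` with within-distance variability, radially anisotropic
planned-endpoint deviations with sd `c_axis * sqrt(d)` (so absolute
deviations grow but *relative* deviations shrink with distance), and a
kinematic marker sharing a fraction kappa of the endpoint deviation.
`simulate_timecourse()` adds the post-target-onset dynamics as an
exponential ramp with latency `t0` and time constant `tau`, for which
the 10%-convergence time has the closed form `t0 + tau * log(10)`.

Defaults (chosen once, for testability of the structure rather than
biological fidelity — the literature does not provide quantitative
channel-noise magnitudes for this preparation): 96 channels, baseline
20 spikes/s, channel noise 0.5 spikes/s, position gains 0.4 spikes/s
per cm, speed gain 0.1 spikes/s per (cm/s), speed relation a = 15
cm/s, b = 2.5 (cm/s)/cm, sigma_s = 2 cm/s, deviation scales c_on = 0.2,
c_off = 0.1 cm per sqrt(cm) (the 2:1 ratio produces ellipse axis
ratios near 2), kappa = 0.5, t0 = 50 ms, tau = 80 ms. The encoding
matrix is drawn once under its own seed and stored, so recovery tests
can compare against ground truth; every simulation takes an explicit
seed and is bit-reproducible.

What the generator does *not* emulate: spiking statistics, unit
turnover across sessions, reaction times, failed or zero-delay trials,
nonlinear or mixed selectivity, and realistic noise correlations
between channels. Passing tests therefore certify the pipeline's
correctness and calibration on data with known structure, not the
biological claims themselves.

A note on one deliberate construction: arc-length distance-independence
is tested under `deviation_scaling = "constant"` with c_on = c_off =
3 cm. The scale matters because endpoint noise is snapped to 16
discrete targets per ring whose spacing grows with radius: much
smaller noise inflates outer-ring arc variance (coarse quantization),
much larger noise compresses inner-ring variance (circular wrap);
around 3 cm the two distortions balance and the generator's true arc
error variance is equal across rings, which is the regime the
distance-independence property describes.

## Numerical choices

* Least squares uses an SVD pseudoinverse with relative singular-value
  cutoff 1e-10, so rank-deficient designs (null-space-projected data)
  are handled without error.
* The delay window is the half-open interval (-200, 0] ms before the
  go cue, avoiding double-counting the go-cue sample.
* Target distances are rounded to 1e-6 cm before "per distance"
  grouping.
* The per-channel task screen is the overall F-test of the
  two-predictor linear model (rate ~ target x + y) against the
  intercept-only model, Bonferroni-corrected by the channel count;
  screened-out channels are flagged, not deleted, and every fit accepts
  an optional channel mask (the default uses all channels).
* Baseline correction is per session ("per day"), not per task: tasks
  are pooled after centering.
* Session-baseline subtraction, condition averaging and the window mean
  are all exactly idempotent/linear, and each is tested against an
  independent loop-based oracle.
* Ellipse coverage is a step function of the scale; the bisection runs
  60 iterations and returns the smallest scale reaching the requested
  average coverage.
* The convergence crossing time is linearly interpolated between the
  two samples bracketing the threshold, giving sub-sample resolution.

## Problem sizes

The test suite simulates 10-100 trials per condition (240-24,000 trials
of 96 channels per instance) and uses 20 seeded replicates for
run-level properties and 200 replicates for null-calibration rate
checks; the acceptance script uses 50 trials per condition for the
structural quantities and 10 per condition for the per-ring decoding
construction. These sizes put Monte Carlo error comfortably inside the
asserted tolerances while keeping any single check under a few minutes
on one CPU.

## Known limitations

* A single line layout cannot identify the spatial plane (one target
  coordinate is constant); the package follows the pooling convention
  (horizontal + vertical fitted together, `pool_trials()`), and errors
  clearly otherwise.
* The speed axis is identifiable only when maximum speed varies; a
  ring task with zero speed noise leaves it undefined (the axis comes
  back as zero).
* The SVM hyperparameters are fixed heuristics (no tuning set is
  simulated); an optional grid search is out of scope.
* CSV is the only interchange format; rate time-series are generated
  in memory rather than persisted.
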