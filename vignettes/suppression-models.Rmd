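---
title: "Filter-based models of excitation and suppression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-based models of excitation and suppression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suppfilt)
```

## The modelling problem

Retinal ganglion cells encode temporally varying light intensity into
spike trains, and much of the structure of their responses — transiency,
gain control, refractoriness — reflects an interplay of excitation and
suppression. `suppfilt` implements four Poisson encoding models of this
interplay for full-field (purely temporal) stimuli, all derived from one
master structure so that their components, constraints, and training are
directly comparable:

* **LN** — a temporal stimulus filter, a monotone static nonlinearity, and
  an output rectifier: `r(t) = f(E(t))`.
* **Subtractive suppression** — a second filter-plus-nonlinearity branch
  whose (monotone) output is subtracted before rectification:
  `r(t) = f(E(t) - S(t))`.
* **Divisive suppression** — a second branch whose bump-shaped output in
  `[0, 1]` multiplies the excitatory signal: `r(t) = f(E(t) * S(t))`.
* **Feedback suppression** (GLM-style) — a filter over the model's own
  recently generated spikes, added to the excitatory signal:
  `r(t) = f(E(t) + (k_fb * n)(t))`.

Each branch output is `B(t) = sum_i w_i g_i(sum_tau k_tau X(t - tau))`:
a causal temporal filter `k` (tap `tau = 0` weights the current frame)
followed by a piecewise-linear nonlinearity in a tent basis `g_i`.  The
master structure used during training writes the model output as

```
r(t) = f( (± B(t) ± P(t)) · M(t) + A(t) )
```

where `P`, `M`, `A` collect the frozen contributions of the branches not
currently being updated (`P` additive before the multiplication, `M`
multiplicative, `A` additive after it).  The output rectifier is a
parametrized softplus `f(x) = m·ln(1 + exp(a·x + b)) + c`, and spike
counts per stimulus frame are Poisson with expectation `r(t)`.

## Constraints and why they matter

Unconstrained, a "suppressive" branch can invert its sign during fitting
and act excitatorily.  The constraint set therefore is part of the model
definition, not a regularizer:

* stimulus filters have unit Euclidean norm and a zero tail (the mean of
  the last five taps is zero), which fixes the gain split between filter
  and nonlinearity and anchors the filter at zero for long lags;
* excitatory nonlinearities (and the subtractive model's suppressive
  nonlinearity) are monotonically nondecreasing with weights bounded
  below by 1e-16;
* the divisive model's suppressive nonlinearity is bump-shaped —
  nondecreasing for negative inputs, nonincreasing for positive ones —
  with its maximum pinned to exactly 1 at zero input and all weights in
  `[1e-16, 1]`.  The unit maximum removes the scale redundancy between
  the two branches, and the bump shape guarantees that any filter
  activation suppresses at least as much as a smaller activation of the
  same sign;
* the feedback filter has no nonlinearity and no norm constraint (its
  scale is meaningful), but keeps the zero-tail constraint;
* the rectifier keeps `a > 0` and `m > 0` so it is nondecreasing; `b` and
  `c` are free.

The tent basis uses 15 uniform knots on `[-3, 3]` (spacing 3/7; the 8th
knot sits exactly at 0, making the bump's unit maximum an equality
constraint on a single weight).  Inputs beyond the knot range are clamped
to the boundary value: with unit-norm filters on unit-variance noise the
filter output rarely leaves `[-3, 3]`, and clamping keeps the boundary
weights identifiable.

## Training

All kinds are fitted by block-coordinate maximum likelihood on the
Poisson objective `-LL = sum_t [r_t - n_t ln r_t + ln(n_t!)]`.  Blocks
are updated in a fixed order — excitatory filter, excitatory weights,
suppressive filter and weights (or the feedback filter), rectifier — with
at most 10 quasi-Newton steps per block and analytic gradients obtained
by the chain rule through rectifier, tent interpolation, and convolution.
The outer loop stops when the relative objective change between
iterations falls below 0.01% or after 100 iterations.  Training restarts
5 times from different initializations (combinations of the
spike-triggered average, the first and last principal components of the
spike-triggered covariance with the STA projected out, deterministic
monotone/bell-shaped weight templates with N(0, 0.1) knot jitter, and
pure noise in the last run); the run with the lowest training `-LL` wins.

Constraints are honoured *throughout* each block update by
parametrization rather than post-hoc projection: filters are optimized
through a tail-projection-plus-normalization map (so every evaluated
iterate has unit norm and zero tail), monotone weights through
`(w_1, increments >= 0)` with box constraints, bump weights through
logistic ratios of neighbouring weights with the center fixed at 1, and
the rectifier through box constraints on `a` and `m`.  A block update
that fails or would increase the objective is discarded, which makes the
objective trace non-increasing by construction.  Initial weight
templates that violate a block's shape class (the bell-shaped template
for a monotone block) are projected by isotonic regression before
training starts.

Numerical choices: rates are floored at 1e-12 inside the likelihood (the
softplus output can be negative only through `c < 0`; the forward pass
clips at 0); the softplus switches to its linear asymptote beyond
`a·x + b = 30`; the first `n_taps - 1` bins of every trace are filter
warm-up (zero-padded stimulus) and are excluded from every likelihood
and every metric so that all models see the identical valid bins.

**Feedback causality.** The feedback filter is applied to the spike train
delayed by one bin, so the rate at bin `t` depends only on spikes
strictly before `t`.  During fitting the observed training spikes feed
the filter (teacher forcing, standard GLM practice); at evaluation the
model is run free: bins are generated sequentially, each bin's count
sampled before the next bin's rate is computed.  Teacher-forced and
free-running rates agree exactly when the supplied history equals the
sampled history.  Because the feedback kind's evaluation is stochastic,
its performance is reported as the mean over 100 free-running
evaluations.

**Convergence rule.** The 0.01% change rule is applied to the outer
iteration (one full cycle over blocks), not per block; applying it per
block would terminate on a single stalled block while others still
improve.

## Metrics

* **Information per spike** (bits/spike): the log-likelihood gain of the
  model over a constant mean-rate predictor, divided by the total spike
  count times `ln 2`.  It needs no repeated trials and is the headline
  performance measure.  Negative values on short samples are reported,
  not clipped.
* **Poisson explained variance**: `1 - dev(r, pred)/dev(r, mean)` with
  the Poisson deviance on trial-averaged frozen-noise firing rates.
* **R²**: ordinary explained variance, used for chirp sweeps inside a
  150 ms sliding window stepped by one frame; each window is labelled by
  the contrast (%) or instantaneous frequency (Hz) at its start frame.
  The *performance range* is the span of the longest contiguous run of
  windows with `R² > 0`; a contiguous band is used because on noisy
  profiles isolated positive windows at the extremes would saturate a
  bare min/max span for every model and mask real differences in
  generalization.  The *low-frequency performance* is the mean over the
  first 10 windows (300 ms) of the frequency sweep.

## Stimuli

White noise is standard normal per frame (zero = mean luminance; one SD
corresponds to 30% contrast, the convention used during recording).
Training/test layout follows the two recording designs: frozen-repeat
mode inserts an identical frozen segment after every block of fresh
noise; pseudo-trial mode holds out the final fifth of each 33.3 s trial.

The chirp stimulus is, at 60 Hz: 120 frames background, 60 frames +100%
contrast (ON step), 60 frames -100% (OFF step), 60 background, a
480-frame frequency sweep (unit amplitude, instantaneous frequency
linear from 0 to 15 Hz), 60 background, a 480-frame contrast sweep (4 Hz
carrier, envelope linear from 0 to 100%), and 60 background — 1380
frames, 23 s.  Two conventions had to be fixed where only the endpoints
are specified: the frequency sweep uses the linear-chirp phase
`phi(t) = 2*pi*(f_max/(2T))*t^2` starting at phase 0, and both sweep
parameters ramp linearly from 0 at the first *sampled* frame to their
maximum at the last, so the nominal endpoints (15 Hz, 100%) are attained
exactly on the frame grid.  Chirp contrast is converted to model input
units by `contrast_to_model_units`; the default 1/0.3 follows from the
30%-contrast-per-SD training convention, and the parameter is exposed
because the conversion used at test time on real recordings is not
determined by the training convention alone.

## The synthetic ground-truth factory

Because the multi-electrode recordings behind the original analyses are
not distributable, every fitting and evaluation path is validated on
synthetic cells with known parameters.  Presets build biphasic
difference-of-gamma excitatory filters (fast/slow, ON/OFF by sign).  The
divisive preset's suppressive filter is a copy of the excitatory filter
delayed by two frames — the configuration typically recovered from fast
cells — with a symmetric bump nonlinearity.  The subtractive preset uses
a kinetically slower, independent suppressive filter and branch
nonlinearities of opposite curvature: a strongly convex
(exponential-type) excitatory nonlinearity and a saturating sigmoid
suppressive one.  This choice is about identifiability, not convenience:
an additive two-branch decomposition `f1(k1·x) − f2(k2·x)` only pins
down its filters when the branch nonlinearities are far from quadratic
over the operating range — for (near-)quadratic branches the filter pair
can rotate along a near-flat likelihood ridge, and with gently curved or
hard-rectified branches we observed maximum-likelihood solutions whose
filters span a different subspace than the generating pair at equal or
better training likelihood.  (The same flexibility is visible in fitted
subtractive models on real cells, whose suppressive filters are far more
diverse than the divisive model's.)  The feedback preset uses a slow,
moderate negative history kernel resembling spike-frequency adaptation.
The rectifier offset is calibrated by root finding so every preset fires
at 10 sp/s (±10%) on white noise.

The default simulated recording is 18,000 training plus 3,600
frozen-test bins at 60 Hz (12 blocks of 1,500 fresh + 300 frozen frames,
about 5 + 1 minutes) — large enough for reliable filter recovery
(excitatory-filter cosine similarity ≥ 0.9 across presets and seeds)
while keeping a full five-restart fit on a desktop CPU in the tens of
seconds; chirp generalization uses 15 repeated trials.  These sizes are
deliberately below the roughly 7 training minutes typical of the
recordings the models were developed on, and the suppression strengths
are chosen so the matched model kind reliably beats a fitted LN model on
held-out information per spike.

What the synthetic cells do *not* emulate: spike sorting artifacts,
slow firing-rate drift, ON-OFF cells, spatial structure, and
cell-to-cell correlations.  Passing the recovery suite therefore shows
the estimator is correct and well-conditioned at realistic signal/noise,
not that real retinas obey these models.

## Unit characterization

The package also implements the descriptive procedures used around the
model comparison: spike-triggered average and covariance features (the
STC is eigen-decomposed in the orthogonal complement of the STA, so the
trivial zero-variance STA direction can never masquerade as the last
component); the classical histogram-nonlinearity LN baseline (empty
histogram bins inherit the nearest non-empty value so lookups at extreme
generator values stay defined); PCA classification of temporal filters
into slow/fast ON/OFF classes with ±0.02 score thresholds (component
signs are fixed so the largest-magnitude loading is positive — the
polarity meaning of each axis should be confirmed against the class-mean
filters); transient/sustained classification by the sustained-to-peak
ratio with a strict 0.2 threshold (a ratio of exactly 0.2 is sustained);
ON-OFF detection by the slope-ratio rule `sL/(|sL|+|sR|) < -0.2`; the
five unit-selection criteria (species rate threshold, split-half
reliability over 20 random trial divisions using R², early/late
stationarity over the first/last 30% of frames, not-ON-OFF, and a
test/train performance ratio of at least 0.6 for all fitted kinds); and
duplicate-unit removal by maximal cliques (via igraph) in the
correlation graph at threshold 0.3, keeping the lowest-index member of
each clique, with overlapping cliques resolved greedily largest-first.

Where the procedure definitions left a choice open, the package fixes it as
follows: split-half reliability uses R² of one half-PSTH predicting the
other; selection criterion 5 measures performance as information per
spike; the early/late stationarity windows are counted in recorded
white-noise frames; the transiency peak window is exactly 200 ms; and
the performance range reports the min/max of qualifying windows without
requiring contiguity.

## Known limitations

* Purely temporal stimuli; no spatial or spatiotemporal filtering.
* Poisson spike generation only; no refractory hard floor beyond what
  the feedback filter learns.
* The block-coordinate scheme guarantees a non-increasing objective, not
  a global optimum; the five-restart schedule is the only safeguard
  against local minima, as in the original fitting procedure.
* The feedback model's suppression acts only after spikes occur, which
  bounds how well it can capture suppression of a response's onset; this
  is a property of the model class, not of the implementation.
* The free-running evaluation of the feedback model carries a structural
  penalty: conditional on the stimulus, each evaluation's sampled spikes
  are independent of the observed spikes, so by Jensen's inequality the
  expected per-evaluation log-likelihood is at most that of the
  evaluation-averaged rate — the stochastic timing of the model's own
  suppression can only cost likelihood.  On data generated by a feedback
  cell whose excitatory branch is itself in the model class, a fitted LN
  model can therefore match or exceed the feedback model's averaged
  free-running score even when the feedback fit is excellent in the
  teacher-forced sense.  This mirrors the empirical pattern that the
  feedback model trails the feedforward suppressive models on real
  recordings, and it is why the recovery suite checks the feedback
  preset's filter recovery but cannot expect the feedback fit to beat the
  LN fit under this evaluation.

## A worked example

```{r example, eval = FALSE}
cell <- make_cell("divisive_off", seed = 1)
rec <- simulate_recording(cell, seed = 1)          # 18,000 + 3,600 bins
fit_div <- fit_model("divisive", rec$stim, rec$counts, rec$schedule,
                     seed = 1)
fit_ln <- fit_model("ln", rec$stim, rec$counts, rec$schedule, seed = 1)
ev_div <- evaluate_model(fit_div, rec$stim, rec$counts, rec$schedule)
ev_ln <- evaluate_model(fit_ln, rec$stim, rec$counts, rec$schedule)
c(divisive = ev_div$info_test, ln = ev_ln$info_test)
```

The divisive fit recovers the generating excitatory filter (cosine
similarity above 0.9 across seeds at the default problem size) and beats
the LN fit on held-out information per spike; `scripts/acceptance.R`
runs this comparison end to end for all presets.
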