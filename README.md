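# suppfilt

Filter-based Poisson encoding models of retinal ganglion cell spiking,
with explicit excitation-suppression interactions, in R.

## The problem

Retinal ganglion cells respond to temporally varying light intensity
with spike trains whose transiency, gain control, and refractoriness
reflect an interplay of excitation and suppression.  The workhorse
linear-nonlinear (LN) model — one temporal filter, one static
nonlinearity, Poisson spiking — has no suppressive component.  This
package implements the LN model and three suppressive extensions inside
one unified ("master") structure, so that the models differ only in how
a second signal interacts with the excitatory drive:

| kind | rate |
|---|---|
| LN | `r(t) = f(E(t))` |
| subtractive | `r(t) = f(E(t) − S(t))`, `S` monotone |
| divisive | `r(t) = f(E(t) · S(t))`, `S` bump-shaped in [0, 1] |
| feedback | `r(t) = f(E(t) + (k_fb ∗ n)(t))`, `n` = own spikes |

Each branch is `B(t) = Σ_i w_i g_i(Σ_τ k_τ X(t−τ))`: a causal temporal
filter followed by a piecewise-linear nonlinearity in a tent basis
(15 knots on [−3, 3]); the common output rectifier is a softplus
`f(x) = m·ln(1+e^{ax+b}) + c`, and spike counts per stimulus frame are
Poisson.  Filters carry unit-norm and zero-tail constraints;
nonlinearities carry shape constraints (monotone, or bump with unit
maximum at zero) that keep the suppressive branches genuinely
suppressive.  Fitting is block-coordinate maximum likelihood with
analytic gradients, constraint-preserving parametrizations, five guided
restarts (spike-triggered average/covariance initializations), and a
0.01% relative-change stopping rule.

The package is for computational neuroscientists who want to fit and
compare these model classes on binned spike responses to full-field
stimuli — or to validate such fitting pipelines on synthetic
ground-truth cells, which the package generates (white noise with
frozen-noise repeats, chirp stimuli with frequency and contrast sweeps,
calibrated model cells).  Evaluation metrics include information per
spike, Poisson explained variance on frozen-noise PSTHs, and
sliding-window R² generalization profiles along chirp sweeps, plus the
surrounding cell-characterization procedures (STA/STC, PCA filter
classes, transiency, ON-OFF detection, unit selection, duplicate-unit
removal).

## A worked example

Simulate a divisive-suppression ground-truth cell, fit the divisive and
LN models to its white-noise responses, and compare on held-out
frozen-noise repeats:

```r
library(suppfilt)

cell <- make_cell("divisive_off", seed = 1)      # calibrated to 10 sp/s
rec  <- simulate_recording(cell, seed = 1)       # 18,000 train + 3,600 test bins

fit_div <- fit_model("divisive", rec$stim, rec$counts, rec$schedule, seed = 1)
fit_ln  <- fit_model("ln",       rec$stim, rec$counts, rec$schedule, seed = 1)

ev_div <- evaluate_model(fit_div, rec$stim, rec$counts, rec$schedule)
ev_ln  <- evaluate_model(fit_ln,  rec$stim, rec$counts, rec$schedule)

round(c(info_div = ev_div$info_test, info_ln = ev_ln$info_test,
        excess = ev_div$info_test - ev_ln$info_test,
        cos_exc = abs(sum(fit_div$model$exc$taps * cell$exc$taps))), 4)
#>  info_div   info_ln    excess   cos_exc
#>    0.0961    0.0913    0.0049    0.9915
```

`info_div`/`info_ln` are held-out information per spike in bits/spike
(log-likelihood gain over a constant-rate predictor, per spike); the
divisive model's excess performance over the LN model reflects the
suppression the LN model cannot express, and `cos_exc` is the cosine
similarity between the fitted and the generating excitatory filter.

## Command-line interface

`exec/suppfilt` wraps the exported functions for shell use:

```sh
suppfilt simulate --preset divisive_off --seed 1 --out sim/
suppfilt fit --kind div --stim sim/stimulus.tsv --spikes sim/spikes.tsv --out model.json
suppfilt eval --model model.json --stim sim/stimulus.tsv --spikes sim/spikes.tsv --out metrics.tsv
```

Stimuli and spike trains are headered TSV (with a JSON sidecar for
segment metadata); models are schema-versioned JSON documents that
round-trip exactly.

See `vignettes/suppression-models.Rmd` for the model definitions,
constraint rationale, training algorithm, and the design decisions
behind the synthetic ground-truth factory.
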