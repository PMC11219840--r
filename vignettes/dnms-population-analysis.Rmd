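---
title: "Calibrated population decoding of synthetic DNMS sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated population decoding of synthetic DNMS sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dnmspop` implements, end to end, the analysis chain used to characterise
perirhinal population activity in a whisker-based delayed
non-match-to-sample (DNMS) go/no-go task, together with a synthetic-session
generator that plants the neural, cholinergic and behavioral effects those
analyses are designed to detect. The generator is first-class, tested code:
every downstream stage — calcium event estimation, the decoding suite, the
choice-selectivity index, the familiarity model, the acetylcholine GLM —
can be exercised and validated without any recorded data.

The package is organised as an analysis workflow: all computation lives in
the package functions, and the numbered scripts under `analysis/` are thin
narrative drivers that run the standard course and write tables under
`results/`.

# The task world

Sessions follow the head-fixed five-stage training design. A trial is
pre-stimulus (1.0 s), sample (1.0 s), delay, test (1.0 s), report (1.5 s)
and a 1.0 s post-trial interval at a 32.6 Hz frame rate. The frame rate is
from the acquisition system; the period durations are not printed anywhere
in the task tables, so these defaults are declared choices of this package
(configurable per stage config), sized to match the figure time axes of
the original experiments.

Per stage: the nonmatch/match split is 0.5/0.5 (T1 optionally ramps
0.9 to 0.5 over five sessions), the held-out posterior-anterior nonmatch
condition enters at T3, the fast/slow split is 0.95/0.05 through T4 and
0.75/0.25 at T5, and delays are 100 ms through T3, 2 s at T4, and a
2/3/4 s mixture with probabilities 0.5/0.25/0.25 at T5.

Choices are drawn from a symmetric-criterion observer: lick probability
`pnorm(d'/2)` on nonmatch trials and `pnorm(-d'/2)` on match trials, which
reproduces the task's printed behavioral equivalences (80% correct at
d' of about 1.68, 70% at about 1.05). Stage-default sensitivities are 0.45
(T1), 1.05 (T2) and 1.68 (T3 onward), anchored to the printed advancement
criteria; they are inputs, not measurements.

## Planted population effects

`planted_effects()` defines the study conditions. Spikes are Poisson per
frame at a 0.4 Hz baseline plus condition-locked rate bumps of 4 Hz at
gain 1; fluorescence is the AR(1) convolution of the spikes (0.5 s decay)
plus Gaussian photon noise on a unit baseline. The per-stage gain
schedules encode the learning trajectory the analyses should recover:

* direction cells: gain 1 down to 0 across T1..T5 on correct trials,
  retained at the naive gain on error trials;
* speed cells: gain 0.2 up to 1 across stages, with a 1.75x error-trial
  bias from T2 onward;
* reward cells: active on hit trials from `reward - lead` to the end of
  the report window, the lead growing 0 to 1.6 s across stages
  (retrograde expansion). An optional AP/PA overlap parameter moves the
  reward code between one shared subspace and two disjoint
  condition-specific subspaces;
* expected-outcome cells: a weak pre-stimulus offset for future-hit
  trials whose preferred class reverses at the report window.

Each neuron draws from its own RNG stream split deterministically from the
master seed, and cell types are assigned by a per-index low-discrepancy
rule, so enlarging a population never perturbs existing neurons. These
sessions emulate trial structure, planted coding subspaces and noise; they
do not emulate real calcium transients' rise kinetics, neuropil
contamination, motion artifacts, electrode drift or correlated network
noise — passing tests therefore validate the analysis chain's logic and
calibration, not its behavior on every pathology of real recordings.

# Calcium event estimation

Fluorescence is floored at the per-neuron bottom 10th percentile (linear
interpolation). Flooring rather than zeroing is a deliberate reading of
"thresholding": it preserves the baseline level that both the shot-noise
statistic and the deconvolution residuals are defined against. The
shot-noise level is the median absolute successive difference divided by
the square root of the frame rate. The AR(1) decay coefficient is
estimated from the lag-2/lag-1 autocovariance ratio — robust to additive
white measurement noise — clipped to (0.5, 0.999) with a flagged fallback
at a 0.5 s decay for degenerate traces.

Deconvolution solves the nonnegative sparse problem
`min 0.5 ||F - c||^2 + lambda ||s||_1` with `c_t = gamma c_{t-1} + s_t`
by the online active-set / pool-adjacent-violators scheme, written in this
package (no R implementation of the algorithm is on CRAN/Bioconductor).
The L1 term telescopes into a per-frame offset of the target trace, after
which pool merging is exactly isotonic regression under the decaying
extrapolation constraint. The unit tests verify the solution against a
box-constrained quasi-Newton solve of the same objective to 1e-6 on short
traces. `lambda` defaults to `v * sqrt(n_frames)` per neuron — a
noise-scaled choice, since no value is printed. Events are divided by the
per-neuron noise level to give the event estimate `s_hat` in
signal-to-noise units; `s_hat` is invariant to per-neuron gain at
`lambda = 0`.

# The decoding suite

Features are window means of `s_hat` per trial, z-scored per neuron across
trials; zero-variance columns map to zero. Decoders are linear max-margin
(support-vector) classifiers at a fixed moderate penalty (cost 1 — none is
printed; configurable), with stratified 10-fold cross-validation. For rare
minority labels (speed, choice) the training split's minority class is
resampled with replacement to match the majority, the whole procedure
repeated (100 times at full scale) and averaged. Ties at decision value
exactly zero fall to the negative (alphabetically first) class.

Significance is calibrated, not assumed:

* label-shuffle nulls refit the decoder on permuted labels (1000 times at
  full scale) and flag observations outside the 5th-95th percentile band;
* cross-temporal decoders (trained on a period or sliding 1 s window,
  tested on sliding 300 ms windows at a 100 ms step) use weight-shuffle
  nulls: the weight vector is permuted across neurons with the bias kept.
  The null is computed under the same cross-validated structure as the
  observed statistic — one permutation applied to every fold model and
  scored on that fold's held-out trials — because an uncrossvalidated
  null is visibly too narrow against a cross-validated observation;
* per-neuron weight significance uses each neuron's own label-shuffled
  weight distribution.

The decodable onset is the start of the first run of two consecutive
significant test windows inside the test-through-report interval. The
single-window reading ("first significant time point") is available as
`n_consecutive = 1`, but with a calibrated 5% per-window false-positive
rate and 300 ms windows sharing two-thirds of their frames at a 100 ms
step, false positives cluster and bias single-window onsets early by
several window steps; requiring two consecutive windows removes that bias
without delaying detection of a sustained signal. Onset-lead recovery is
asserted on the median across seeded simulations: the reward time itself
jitters trial-to-trial (reward is delivered at the first report-period
lick), so single-seed onsets carry irreducible jitter that the
lead-difference median cancels.

Cross-session decoding applies a frozen model to the same window of
another session of the same population (features z-scored within the test
session). Cross-condition decoding trains hit vs non-hit on report
activity of one nonmatch condition (plus half the match trials) and tests
cross-temporally on the other; the 300 ms window ending at the end of the
test period summarises generalization strength.

# Choice selectivity

For neurons with significant speed-decoder weights, the stimulus response
(SR) is the peak of the trial-averaged event estimate over the sample or
test period — trial-averaged first, peak second, the declared reading of
an ambiguous definition — and choice selectivity is
`(SR_error - SR_correct) / (SR_error + SR_correct)`. Zero-denominator
records are dropped (the ratio is undefined), not set to zero.

# The familiarity model

A noisy-ReLU autoencoder (inputs: four condition prototypes on
`{-1,1}^2`, direction x speed, plus 2-D Gaussian noise sd 0.5, projected
by a fixed random Gaussian matrix to 10 dimensions; hidden noise sd 1
after the ReLU, at training and readout time) is trained with minibatch
ADAM (lr 0.002, batch 10, 50 epochs) on
`beta_r * MSE + beta_c * cross-entropy(direction) + beta_s * L1(hidden)`
with weights 0.1 / 1 / 1. Gradients are closed-form backpropagation
(finite-difference checked in the unit tests). The hidden width is not a
published constant; the default equals the input width (10). Weights
initialise as centered Gaussians scaled by `1/sqrt(fan_in)`.

The familiarity signal is the signed difference between reconstruction
and input. The per-epoch readout is an L2-regularised logistic regression
(ridge weight `1/n_train` on unscaled features, the default of the
standard scientific-python logistic classifier) with stratified 5-fold
CV. The regularisation matters: an unpenalised readout extracts residual
direction information at ceiling and shows no dissociation, whereas the
norm-limited readout is sensitive to the relative magnitude of each
component in the familiarity signal, which is exactly what training
reshapes.

What the model reproduces at the default configuration, averaged over 20
simulations: direction decoding of the familiarity signal collapses from
about 0.97 in the first epochs to about 0.68 at epoch 50, and speed
exceeds direction at the final epoch in nearly every simulation (sign
test); the reconstruction-only variant (`beta_r = 1`, others 0, lr 0.01)
shows no such dissociation — both labels decay together. One known
limitation: the absolute speed accuracy does not rise over epochs here.
At epoch 1 the reconstruction is still near zero, so the familiarity
signal is essentially the negated input and speed is readable at its
input ceiling (~0.96) from the start; it declines mildly (~0.87) while
direction collapses. The dissociation — speed increasing relative to
direction, and dominating it at the end of training — is the reproduced
phenomenon; the early-epoch speed ceiling is a property of this
implementation's readout applied to an untrained network.

# The acetylcholine GLM

Task variables are frame-rate boxcars (pre-stimulus, each stimulus
direction over its sample+test frames, post-trial, and a 300 ms reward
boxcar — 10 frames at 32.6 Hz), plus lick trains convolved with a
10-sample Gaussian kernel (sd 2 samples, unit mass; the sd is not printed)
split into pre-reward and post-reward licking by the reward time on hit
trials (all licks on miss/FA/CR trials are pre-reward). The identity-link
Gaussian model is fit with an L1 path of 6 penalties, log-spaced three
decades down from the smallest all-zeroing penalty (only the count is
printed), selected by 4-fold cross-validated deviance. Deviance is the
residual sum of squares at unit dispersion, so `AIC = 2k + deviance` is
comparable across nested fits; `k` counts nonzero fitted parameters
including the intercept (an all-parameters mode is available). Factor
importance is `AIC_partial - AIC_full` after refitting without that
factor's covariates, directions grouped as one factor.

On the generator's cholinergic trace — a pre-stimulus transient on every
trial plus a pre-reward lick-locked component, nothing locked to reward
consumption, z-scored per trial — the pre-stimulus factor dominates the
ranking, pre-reward licking is second, and reward/post-reward licking
explain nothing, which is the planted structure.

# Behavior rules

`dprime()` clamps degenerate rates at the half-count correction
`1/(2N)`. Stage advancement requires the stage threshold (0.45 at T1,
1.68 from T2) for two consecutive sessions. The adaptive rules follow the
printed table cells exactly: punishment over a 50-trial window (<70%
correct: +1 s timeout to 10 s, then +1 air puff to 5 beyond 7 s; >50%
misses: -2 s / -2 puffs to the 2 s / 0 floors) and stimulus-probability
corrections over a 20-trial window. The primacy/recency criterion is
printed as `(X/Y - 0.5) > 0.55`; the package implements that ratio form
literally as the default and ships an `X - Y` difference mode, since the
printed expression reads like a possible typo for the difference.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced but
statistically meaningful sizes, chosen once as this package's study
conditions: null calibration over 200 label-independent sessions of 30
trials x 8 neurons with 100-shuffle nulls and 5-fold CV (under label
exchangeability the exceedance rate is ~5/101 regardless of null size);
onset recovery over seeded lead-0 vs lead-1.5 s pairs with a 2 s test
period so the 1.5 s lead lies inside the measurable test+report span;
sign-flip detection over 20 seeds of 150-trial, 40-neuron sessions; the
familiarity model at 20 simulations; course replicas at 1-2 sessions per
stage, 100-150 trials, 30-40 neurons. Full-scale settings (1000-shuffle
nulls, 100 resamples, 100 simulations) remain the documented defaults of
the user-facing functions.

Other numerical choices: percentiles use R's default linear interpolation
(type 7); window boundaries are half-open in seconds converted by floor
to frames; sliding test windows that overrun a trial are truncated with a
warning; degenerate kernel fits fall back and are flagged; session
bundles round-trip through 17-significant-digit text, which is exact for
IEEE doubles.

# Known limitations

* The generator's Poisson-plus-AR(1) world has no correlated noise,
  drift, or nonstationarity; calibration results transfer to real data
  only insofar as those are absent or handled upstream.
* The familiarity model's absolute speed-accuracy rise is not reproduced
  (see above); the direction collapse and final dissociation are.
* Cross-temporal windows are anchored to trial starts; sessions mixing
  delay lengths (T5) align the test/report anchors at the modal delay.
* The weight-shuffle null is a permutation of fitted weights with the
  bias kept; refitting the bias per shuffle is a documented alternative
  the package does not implement.
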