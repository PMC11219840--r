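# dnmspop

Synthetic delayed non-match-to-sample (DNMS) sessions and the calibrated
population-analysis chain that characterises them.

## The problem

In a whisker-based DNMS go/no-go task, a rodent feels a sample stimulus
(anterior or posterior rotor direction, fast or occasionally slow speed),
waits through a delay, feels a test stimulus, and licks for water only
when the two directions differ (non-match). Across five training stages
(T1–T5), population recordings in perirhinal cortex show a characteristic
learning signature: direction information fades from stimulus responses
while speed information grows (a sensory prediction-error pattern),
reward-outcome information becomes decodable progressively *earlier* in
the trial (retrograde expansion of the stimulus–reward association),
expected-outcome information is present before the stimulus and reverses
sign at the reporting period, and bulk acetylcholine is dominated by a
pre-stimulus transient.

`dnmspop` implements the full analysis chain behind those conclusions and
a synthetic-session generator that plants each effect, so every analysis
can be validated — including its false-positive calibration — without any
recorded data. Its audience is anyone building or auditing population
decoding pipelines for trial-structured imaging experiments.

## What is inside

* **Trial world** — stage-configured schedules (nonmatch/match, AP/PA,
  fast/slow, delay mixtures), a symmetric-criterion d′ observer
  (80% correct ↔ d′ ≈ 1.68), stage-dependent lick trains, Poisson + AR(1)
  calcium populations with planted direction / speed / reward /
  expected-outcome codes, and a cholinergic trace.
* **Calcium events** — baseline flooring at the 10th percentile,
  shot-noise level `v = median|F_{t+1} − F_t| / √f_r`, AR(1) kernel fit,
  OASIS-style pool-adjacent-violators deconvolution
  (`min ½‖F − c‖² + λ‖s‖₁`, `s ≥ 0`), and signal-to-noise normalised
  event estimates ŝ.
* **Decoding** — linear max-margin decoders with stratified 10-fold CV,
  minority resampling for rare labels, label-shuffle nulls with 5th/95th
  percentile bands, cross-temporal decoders (1 s train / 300 ms sliding
  test windows) with cross-validated weight-shuffle nulls, decodable
  onset, cross-session and cross-condition (AP↔PA) generalization,
  decision-variable projection, per-neuron weight significance, and
  decoder-vs-behavior Pearson correlation.
* **Choice selectivity** — `(SR_error − SR_correct)/(SR_error + SR_correct)`
  over speed-significant neurons.
* **Familiarity model** — a noisy-ReLU autoencoder with a direction
  read-out unit, trained with ADAM on
  `β_r·MSE + β_c·cross-entropy + β_s·L1(hidden)`, and a ridge-logistic
  readout of the familiarity signal (reconstruction − input) per epoch.
* **Acetylcholine GLM** — boxcar + lick-kernel design matrix, L1 Normal
  GLM (6 penalties, 4-fold CV), `AIC = 2k + deviance`, and ΔAIC
  task-factor importance.
* **Behavior rules** — d′, stage advancement, and the adaptive
  punishment / stimulus-probability corrections.

## Worked example

```r
library(dnmspop)

# A learned-stage session with the default planted effects
cfg <- stage_config("T3")
b   <- simulate_session(cfg, n_trials = 150,
                        fx = planted_effects(n_neurons = 40), seed = 7)
round(dprime_trials(b$trials), 2)
#> [1] 1.6

# Calcium event estimation and a direction decoder on correct trials
ev <- estimate_events(b$F, b$frame_rate_hz)
ok <- b$trials$outcome %in% c("hit", "CR")
f  <- window_features(ev, b$trials[ok, ], "sample")
m  <- fit_decoder(f, b$trials$sample_dir[ok], folds = 10, seed = 1)
null <- label_shuffle_null(f$X, b$trials$sample_dir[ok], folds = 10,
                           n = 200, seed = 1)
c(accuracy = m$accuracy, pct95 = null$pct95)
#>  accuracy     pct95
#> 1.0000000 0.5936014
```

The decoder reads the planted direction code far above the 95th
percentile of its label-shuffle null — at stage T3 the planted gain is at
half its naive value and still decodable; by T5 it is gone and the same
call lands inside the band. The numbered scripts under `analysis/`
(`01_simulate_course.R` … `06_behavior_rules.R`) run the full course —
simulation, events, stage-resolved decoding with onsets, selectivity,
the familiarity model, the GLM and the closed-loop behavior rules — and
write their tables under `results/`.

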