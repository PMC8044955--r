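# fogcast

Freezing of gait (FOG) — the sudden inability to start or continue walking —
affects most people with longstanding Parkinson's disease. Cueing delivered
*before* an episode can shorten or avert it, so the useful problem is
**prediction**: recognizing the pre-freeze deterioration phase (preFOG) from
body-worn inertial sensors early enough to act. `fogcast` is an R package for
building and evaluating such a predictor, aimed at researchers in wearable
gait analysis and digital biomarkers.

## What it implements

* **Synthetic cohort generator** — seeded multi-IMU recordings (7 sensors ×
  3-axis accelerometer + 3-axis gyroscope at 100 Hz) with quasi-periodic
  gait, a configurable pre-freeze amplitude/jitter ramp, FOG episodes with
  elevated 3–8 Hz "trembling" power, and burst outliers; plus exact event
  annotations.
* **Preprocessing** — per-channel replacement of samples outside the
  [2.5th, 97.5th] percentile interval by the channel median; zero-phase
  Butterworth high-pass detrending; sliding-window segmentation where
  FOG-overlapping windows are discarded and a window is labeled `prefog`
  when its final sample falls within `prefog_duration` points of a FOG
  onset.
* **Feature bank** — 22 time/frequency features per channel window
  (max, min, mean |x|, range, RMS, mean, sd, skewness, kurtosis, variance,
  waveform/crest/clearance/impulse factors, reciprocal CV, non-centered
  moment coefficients, energy-operator kurtosis, and four spectral
  statistics), assembled into a 7 × 6 × 22 = **924-column matrix** and
  z-scored on training rows only.
* **Orthogonal design** — the Taguchi **L16(4³)** array over window size
  {128, 256, 400, 500}, step {5, 10, 20, 30} and preFOG duration
  {150, 250, 500, 600} sampling points (1 point = 10 ms); balance
  verification; main effects, window×preFOG interaction, and
  LogWorth = −log₁₀(p) analysis; best-level selection.
* **Classifier** — random forest with the optimized tuple
  (n_estimators = 800, max_features = 0.1 → 92 candidates per split,
  max_depth = 4, min_samples_split = 4, min_samples_leaf = 4), trained and
  scored under leave-one-patient-out cross-validation with window-based
  F1 = 2TP/(2TP+FN+FP) and Cohen's kappa; top-K feature selection by
  fold-honest impurity importance.
* **Episode evaluation** — merging preFOG predictions into alarms and
  scoring **hit rate**, per-alarm **false-positive rate**, and **mean
  prediction time (MPT)** against annotated onsets, with a
  circular-shift permutation null for the hit rate.

## Worked example

```r
library(fogcast)

# a 6-patient synthetic cohort: 45 s each, FOG onsets at 15 s and 36 s
cohort <- simulate_cohort(seed = 7)

# the 16-run orthogonal design over the segmentation hyperparameters
design <- build_l16_4_3()
verify_orthogonality(design)$pass
#> [1] TRUE

resp <- run_design(design, cohort$recordings, cohort$annotations,
                   rf_params(seed = 7), seeds = 7)

# kappa is the selection response (prevalence-corrected across runs);
# the F1 effects are analyzed the same way
eff <- effects_analysis(design, resp, "kappa",
                        interactions = list(c("window_size", "prefog_duration")))
best <- select_best(eff)

sc <- end_to_end_eval(cohort$recordings, cohort$annotations, best,
                      rf_params(seed = 7),
                      horizon_s = lead_horizon_s(best))
sc
```

On this cohort the run above selects the segmentation parameters
`(window_size, step, prefog_duration) = (500, 30, 150)` — a 5 s window, a
300 ms step and a 1.5 s preFOG label — and prints

```
<episode_score> hit rate 100.0% (12/12), FPR 14.3% (2/14 alarms), MPT 6.10 s
```

i.e. every one of the 12 FOG episodes was preceded by an alarm inside the
parameter-implied 6.5 s matching horizon, 2 of the 14 alarms were not
followed by an onset, and hit alarms led the onset by 6.10 s on average —
ample lead time for a cueing intervention. A 100-permutation circular-shift
null puts the chance hit rate at 0.33 (median), so this alarm stream is far
from accidental (p ≈ 0.01). (Numbers are for seed 7 and the default cohort;
other seeds give similar magnitudes.)

The same workflow is scriptable end to end:

```sh
Rscript inst/cli/fogcast.R all --config cfg.yaml --seed 7 --out out/
```

which writes `design.csv` (16 rows), `responses.csv`, `effects.json`
(LogWorth table + selected levels), `episode_score.json`, and a
`manifest.json` with the config hash; rerunning with the same config and
seed reproduces the artifacts byte for byte.

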