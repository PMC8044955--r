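---
title: "Predicting freezing of gait from wearable IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting freezing of gait from wearable IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fogcast)
```

## The problem

Freezing of gait (FOG) is an episodic inability to start or continue walking
that affects a majority of people with longstanding Parkinson's disease.
Because rhythmic cueing can shorten or even avert an episode when delivered
early enough, *predicting* an upcoming freeze from body-worn inertial sensors
is more useful than merely detecting one. `fogcast` implements a complete
prediction pipeline around one key hypothesis: gait deteriorates in a
detectable way during a *preFOG* phase immediately before the freeze. The
classifier's job is to recognize preFOG windows; an episode-level evaluation
then asks whether the resulting alarms anticipate the annotated FOG onsets.

The pipeline stages are

1. multi-IMU signal acquisition (here: simulation),
2. cleaning (percentile-based outlier replacement, high-pass detrending),
3. sliding-window segmentation with three-class labeling
   (normal / preFOG / FOG, with FOG windows removed from training),
4. a bank of 22 time- and frequency-domain features per channel
   (7 IMUs x 6 channels x 22 = 924 features),
5. a random-forest preFOG-vs-normal classifier under leave-one-patient-out
   (LOPO) cross-validation,
6. a Taguchi L16(4^3) orthogonal design over the three segmentation
   hyperparameters (window size, step, preFOG label duration), with
   main-effect / interaction / LogWorth analysis and best-level selection,
7. episode-based evaluation: hit rate, false-positive rate, mean prediction
   time (MPT).

## The synthetic cohort

No public recordings accompany the study design this package follows, so a
seeded generator stands in for patient data. Normal gait on every channel is
a quasi-periodic oscillation at the step frequency (default 1.8 Hz, plus a
0.3-amplitude second harmonic) with per-sensor random phases and amplitude
scalings, plus white noise (default sd 0.1 against unit gait amplitude).
During a FOG episode the gait amplitude collapses to 25% and a "trembling"
oscillation inside the conventional 3--8 Hz freeze band is added (default
amplitude 2). Across a fixed 3 s ramp before each onset the gait amplitude
decays linearly by `prefog_drift` (default 0.6) and cycle-period jitter
grows by the same fraction. Burst outliers of +/-10 channel standard
deviations are injected with probability 0.005 per sample to exercise the
percentile cleaner on both tails.

Two choices deserve emphasis:

* **The physical preFOG ramp (3 s) is deliberately independent of the preFOG
  *label* duration being optimized.** The true extent of pre-freeze
  deterioration is unknown in practice; the orthogonal design scans label
  durations (1.5--6 s) against a fixed underlying ramp, exactly the situation
  the optimization is meant to resolve.
* **The amplitude-decay + jitter model is a stand-in, not a claim about real
  preFOG morphology.** Passing tests show the pipeline recovers a planted
  signature of this kind; they do not show that real pre-freeze gait looks
  like this.

The standard test cohort is 6 patients x 45 s with two 3 s episodes per
patient (onsets at 15 s and 36 s). The recording must be long enough that
normal windows remain well represented at every studied label duration: with
5 s windows and a 6 s label zone, a normal window needs an 11 s clean
stretch. Shorter, denser fixtures invert the class balance (preFOG becomes
the majority class at long label durations), which both degenerates some
design runs and inflates their F1 via prevalence -- an artifact of fixture
scale, not of the method. Real walking protocols are minutes long with
sparse episodes; 45 s with two episodes is the smallest layout that
preserves that character while keeping the full 16-run design tractable on
one CPU.

## Preprocessing

Per channel over the whole recording, samples strictly outside the empirical
[2.5th, 97.5th] percentile interval are replaced by the channel median
(computed on the original series). Detrending uses an order-4 Butterworth
high-pass applied forward-backward (zero phase); the 0.3 Hz cutoff removes
drift and DC while leaving the gait band (>= 0.5 Hz) essentially untouched
(< 1% attenuation at 2 Hz). Order of operations is outliers first, then the
filter. All three window parameters are in sampling points (1 point = 10 ms
at the fixed 100 Hz rate).

Candidate windows start every `step` points; any window overlapping a FOG
event by one sample is discarded, which both removes FOG data from training
and prevents leakage across the onset boundary. A surviving window is
labeled `prefog` exactly when its **final** sample falls in the zone
`[onset - prefog_duration, onset)`. Anchoring at the last sample keeps the
label causal -- it reflects the window's most recent instant, which is what
an online predictor would act on. Zones are clipped at the recording start
and windows inside a clipped zone keep the prefog label.

## The feature bank

Eighteen time-domain and four frequency-domain features are computed per
channel window (`feature_registry()` lists them). All moments use the
population (1/Ns) normalization. Conventions worth noting:

* F14/F15 are the *non-centered* third/fourth moments of `x/sd` --
  intentionally distinct from the central skewness/kurtosis F8/F9.
* F16 (clearance factor) uses the conventional form
  `max|x| / (mean sqrt(|x|))^2`. The tabulated definition this bank follows
  prints F16 identically to the crest factor F12, almost surely a
  typesetting loss; `strict_f16 = TRUE` reproduces that duplicate exactly.
* F21 is the *root*-mean-square frequency (the square root is applied, per
  its name); F22, the amplitude-weighted variance of frequency about the
  center frequency, is left unrooted.
* The spectrum is the raw (untapered) one-sided DFT with `Nfft = Ns`, no
  zero padding, DC bin excluded so detrending residue cannot dominate the
  spectral centroid.
* Degenerate windows (zero sd or zero mean absolute value, all-zero
  spectrum) map the affected ratio features to 0 and are flagged;
  random-forest training requires finite inputs.

Standardization is z-scoring with mean and population sd estimated on
training rows only; test rows reuse the training parameters, and
zero-variance columns pass through flagged. Feature columns are named
`sensorS_<channel>_Fkk` in fixed sensor-major, channel-minor, feature-minor
order so selection reports are reproducible.

## The orthogonal design and effects analysis

The three segmentation hyperparameters take four levels each (window size
{128, 256, 400, 500}, step {5, 10, 20, 30}, preFOG duration
{150, 250, 500, 600} points). The full factorial would need 64 runs; the
L16(4^3) orthogonal array covers the space in 16 runs with every level of
every factor appearing exactly 4 times and every pairwise level combination
exactly once (`verify_orthogonality()` checks the general equal-frequency
strength-2 property, of which exactly-once is the L16 special case).

For each run the pipeline is executed end to end and window-based F1
(preFOG positive class, confusion counts pooled over LOPO folds) and Cohen's
kappa are recorded. Effects analysis fits a linear model of the response on
the factors and reports LogWorth = -log10(p) per term. With a single
replicate the 16-run layout cannot support full categorical interactions
(4-level mains + a 4x4 interaction saturate the design), so when an
interaction is requested the factors are coded numerically (centered level
values) and the interaction enters as a product term; with replicated runs,
or when only main effects are requested, 4-level categorical ANOVA is used.
Both codings are exposed and recorded in the result. `select_best()` picks,
per factor, the level with the best mean response, breaking exact ties
toward the cheaper and more causal setting: smaller window, larger step,
shorter label duration.

**Which response drives selection.** Both F1 and kappa are recorded and
analyzed for every run, but the pipeline selects levels on **kappa**. The
reason is structural: the preFOG label duration mechanically changes the
preFOG prevalence across design runs (a 6 s zone labels four times as many
windows as a 1.5 s zone), and F1's no-skill baseline rises with prevalence
-- at fixture scale a run with 600-point labels approaches 50% prevalence,
where predicting "preFOG" everywhere already yields F1 near 0.67. F1 level
means are therefore not comparable across the label-duration factor, and
F1-driven selection drifts toward long labels whose kappa is near zero.
Cohen's kappa is prevalence-corrected and comparable across runs. Selection
by F1 remains available by passing the F1 effect summary to
`select_best()`.

## The classifier

The random forest uses the optimized tuple (n_estimators = 800,
max_features = 0.1, max_depth = 4, min_samples_split = 4,
min_samples_leaf = 4) as defaults; with 924 features, max_features = 0.1
gives 92 candidate features per split. Training is always
leave-one-patient-out: standardization parameters and (for top-K selection)
feature rankings are computed inside the training fold only. Because FOG
windows are removed, the model is a binary preFOG-vs-normal classifier. F1
is reported for the preFOG class; kappa is Cohen's kappa on the 2x2 window
confusion; fold metrics are pooled by summing confusion counts (micro), with
macro averaging available. Class weights are unweighted by default, with an
optional balanced flag. Top-K selection ranks columns by mean impurity
importance across folds, re-runs LOPO per K, and breaks ties by higher
kappa, then smaller K; importances are also aggregated per base feature id
(F01..F22) for compact reporting.

## Episode-based evaluation

Maximal runs of consecutive preFOG predictions (optionally bridging up to
`gap_tolerance_windows` normals) merge into alarms spanning the first
window's start to the last window's end. An episode is a hit when an alarm
*starts* within the matching horizon before its onset; prediction time runs
from that alarm start, the actionable cueing moment. The false-positive rate
is per alarm (alarms unconfirmed by an onset within the horizon after their
start), since normal gait has no natural episode denominator. Alarms
starting inside an ongoing FOG episode are ignored: FOG data were excluded
from training, and online behaviour during a freeze is out of scope. MPT
averages over hit episodes only.

The horizon needs care. `episode_metrics()` defaults to 6 s, the largest
label duration under study. But an alarm is anchored at its first window's
*start*: a window whose final sample touches the far edge of the label zone
starts `window_size + prefog_duration` points before the onset, i.e. a
structurally correct alarm can lead the onset by up to 11 s at the largest
settings, and a 6 s horizon would score it as a miss plus a false alarm.
`lead_horizon_s()` computes this parameter-implied lead, and the end-to-end
pipeline evaluates with it. The permutation null (circularly shifted alarms)
uses the same horizon, so a longer horizon raises the chance level as well
-- beating the null still requires genuine temporal alignment.

Whether an alarm stream anticipates onsets better than chance is tested by
circularly shifting each patient's alarms by a uniform random offset 100
times and recomputing the hit rate; the one-sided p-value uses the add-one
estimator. On the standard cohort with `prefog_drift = 0.6` the observed hit
rate beats this null; with `prefog_drift = 0` (no planted signature) it
stays inside the null's 90% band.

## Numerical and degenerate-input conventions

* All sample coordinates are 0-based, half-open `[start, end)`.
* Percentiles use R's default (type 7) linear interpolation; replacement is
  strict (`<` / `>`), so a constant channel passes through unchanged.
* A design run whose labeling yields a single class records missing metrics
  with a logged cause and is excluded from effect fits with a warning;
  `select_best()` refuses to select over missing level means.
* F1 with TP = FP = FN = 0 is defined as 0 and flagged; kappa with chance
  agreement 1 is defined as 0; an empty alarm stream has false-positive
  rate 0 with a flag and leaves MPT missing.
* Every random stage derives its seed deterministically from one global
  seed; identical configuration and seed reproduce every artifact byte for
  byte.

## Problem sizes used by the tests and the acceptance script

The formula-oracle suites use 1000 random windows; episode metrics are
checked against a brute-force matcher on 200 random layouts; effect-recovery
simulations use 100 replicates at noise sd 0.01. The end-to-end acceptance
path runs the full 16-run design on the 6 x 45 s cohort with the default
forest (800 trees), then retrains at the selected optimum and evaluates
episodes against a 100-permutation null. These sizes are the package's
standard fixture scale; all are arguments, so larger studies are a config
change.

## Known limitations

* The simulator has no biomechanical body model, no distinct turn/doorway
  regimes, and no magnetometer channels; sensors differ only by phase and
  gain. Results on it validate the pipeline's mechanics and statistics, not
  clinical performance.
* At fixture scale the preFOG prevalence grows with the label duration,
  which inflates the window F1 of long-label runs relative to what sparse,
  minutes-long clinical recordings would show; kappa is less sensitive to
  this and is reported alongside F1 throughout.
* The exact linear-model conventions behind published LogWorth values from
  commercial DOE software are not reproduced; this package documents its own
  coding (numeric product terms vs categorical ANOVA) instead.
* Patient-dependent (within-patient) evaluation is intentionally absent:
  all reported metrics are leave-one-patient-out.
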