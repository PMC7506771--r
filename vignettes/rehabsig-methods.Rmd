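---
title: "Models and methods in rehabsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rehabsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabsig)
```

rehabsig implements the signal-processing chain of a wearable ECG/EMG
monitor for upper-limb rehabilitation training, together with a seeded
synthetic-signal generator and a closed-loop simulation of an adaptive
pneumatic-glove controller. This vignette explains the models, the
tunable parameters and the design decisions, so a reader can judge what
the package's tests do — and do not — establish about real recordings.

## The monitoring problem

During repetitive glove-assisted hand training, two physiological signals
carry the information the trainer needs: the electrocardiogram (ECG),
whose beat-to-beat R–R intervals reveal whether the subject is in an
excited or a fatigued state, and the two-channel surface electromyogram
(EMG) over the flexor carpi radialis (FCR) and extensor carpi radialis
longus (ECRL), whose intensity tracks muscle effort and discriminates
flexion-type from extension-type hand motions. The package processes both
streams and feeds the result to a pressure controller for the assisting
glove.

## ECG conditioning and QRS detection

The conditioning chain is, in order:

1. **Low-pass filtering** (`lowpass_filter`, default 40 Hz). A 4th-order
   Butterworth filter applied forward and backward (`signal::filtfilt`),
   so the phase response is zero and R-peak timing is not shifted. The
   cutoff keeps the QRS energy while rejecting powerline pickup and EMG
   crosstalk.
2. **Baseline removal** (`remove_baseline_median`, default 600 ms
   window). The baseline is estimated as a sliding-window median and
   subtracted. 600 ms is longer than any QRS complex (so beats do not
   distort the estimate) and much shorter than respiration-scale wander
   (~0.3 Hz), which is therefore tracked and removed. Edges are handled
   by reflection padding.
3. **Artifact suppression** (`suppress_artifacts`). Electrode-motion
   transients are short, large spikes. Each sample's residual against a
   short (14 ms) running median is compared with `k_mad = 8` times the
   running median absolute deviation of that residual, plus a small
   absolute floor of 0.1 V. The short median tracks smooth physiological
   waves (their residual is negligible) but not isolated spikes, so only
   spikes cross the threshold; flagged samples and a small neighborhood
   are replaced by linear interpolation. The absolute floor matters on
   very clean traces, where the MAD is nearly zero and a pure
   MAD-proportional threshold would clip genuine QRS curvature. On a
   noise-free trace no sample crosses the threshold and the signal passes
   through bit-identically.

**R-peak detection** (`detect_r_peaks`) follows the differential-threshold
idea: candidate peaks are local maxima located by the sign change of the
first-order difference; within each 10-s processing chunk the amplitude
threshold is half the largest candidate amplitude (discarding P and T
waves, whose amplitude is well under half of R's); finally, candidates
closer together than the minimum physiological R–R interval (300 ms,
i.e. 200 bpm) are resolved by keeping the larger one. Chunking bounds the
effect of slow amplitude drift on the half-maximum rule. P/Q/S/T marking
(`mark_waves`) is provided as annotation only and feeds nothing
downstream.

From the peaks, `compute_rr` forms the R–R intervals and `hrv_windows`
slides a window of `k = 10` beats reporting per window the *variation*
(max − min), mean R–R, SDNN and RMSSD.

## Fatigue classification

Two detectors are provided.

* **Threshold rule** (`rule_fatigue`): fatigue is declared when the R–R
  variation of 10 consecutive measurements falls below 5 ms — a regular
  rhythm. The comparison is strict (`variation < 5 ms`).
* **Linear SVM** (`train_svm` / `classify_status`): windows of 10
  intervals (stride 5) are summarized by mean R–R, SDNN, RMSSD and
  variation, standardized by learning-phase statistics stored in the
  model, and classified by a linear-kernel SVM (`e1071::svm`). The
  kernel and feature set are deliberately small and interpretable; the
  two classes are separated by orders of magnitude in the spread
  features under the generator's default conditions, so a linear
  boundary suffices. Labels are smoothed by a centered rolling majority
  over 3 windows to prevent alert chatter, and an alert event is emitted
  at each excited-to-fatigue transition. Learning-phase labels can come
  from the rule detector (self-supervised bootstrap) or be supplied
  explicitly.

## EMG features and motion discrimination

`rms_segments` computes the root mean square sqrt(sum(v_i^2)/N) over
consecutive non-overlapping segments of `N = 200` samples (200 ms at the
1 kHz default rate). `calibrate_rms_max` implements the pre-training
benchmark: three maximal-effort trials, each reduced to its maximum
segment RMS, averaged into the benchmark RMS_M. `normalize_rms` divides
by RMS_M, giving the dimensionless RMS_N; values above 0.95 are annotated
as possibly saturated, because the RMS feature stops tracking intensity
for very strong contractions and no alternative computation is attempted.

`segment_activity` extracts maximal runs of segments with RMS_N at or
above 0.2 lasting at least 3 segments; runs separated by a single
sub-threshold segment are merged. Both thresholds are package defaults
(configurable), chosen so that a 0.1 V resting baseline against a ~2 V
calibration maximum (RMS_N ≈ 0.05) never triggers while a half-intensity
burst (RMS_N ≈ 0.5) always does.

`classify_motion` applies the two-channel dominance rule: FCR intensity
above ECRL indicates the flexion-type group (forearm pronation, finger
flexion), the converse indicates the extension-type group (hand closing,
wrist extension); an exact tie is reported as indeterminate rather than
as an error. Two channels cannot separate the four motions individually,
so the package reports the dominance *group* and accepts per-motion
labels only from ground truth.

## The synthetic generators

All ground-truth testing runs on the generator module; every random draw
goes through an explicitly passed seed and leaves the caller's RNG state
untouched.

* **R–R series** (`gen_rr_series`): Gaussian jitter around a mean
  interval — 30 ms SD at mean 800 ms for the excited state, 1 ms SD at
  900 ms for fatigue. Fatigue jitter is rejection-resampled into
  ±2.45 ms, so every 10-interval window has range < 5 ms by
  construction; excited windows whose range happens to fall below 5 ms
  are redrawn. These constructions make the two states unambiguous with
  respect to the threshold rule, which is what a correctness test needs;
  real R–R series are autocorrelated and non-Gaussian, so classifier
  accuracies measured here are upper bounds, not clinical estimates.
* **ECG** (`gen_ecg`): one PQRST complex per beat as a sum of five
  Gaussian bumps (amplitudes R = 1.0, Q = −0.1, S = −0.2, P = 0.15,
  T = 0.3 in units of the R amplitude; widths 12/10/10/25/60 ms), placed
  at the cumulative interval times; the analytic R-apex times are the
  ground truth. Noise is additive: sinusoidal baseline wander, 50 Hz
  powerline, white noise, and spike-like motion artifacts of 2–10 ms —
  the `ambulatory` preset uses 0.2 V wander at 0.3 Hz, 0.05 V powerline,
  0.03 V white noise and 4 artifacts/min of 2 V. The template is not a
  dynamical cardiac model; morphology variability, ectopy and electrode
  contact physics are out of scope.
* **EMG** (`gen_emg`): white noise band-passed to 20–450 Hz, normalized
  to unit RMS and multiplied by a trapezoidal envelope (100 ms ramps)
  per motion window, over a 0.1 V resting floor. Inside a window the
  dominant channel's envelope is 2.0 V and the other channel's 1.0 V by
  default (dominance ratio 2, configurable down to 1.2), matching the
  ~2 V intensity scale of maximal forearm contractions. Motor-unit
  structure and inter-muscle crosstalk are not modelled.
* **Sessions** (`gen_session`): one motion bout per minute (four 3-s
  bursts cycling through the four motions), ECG running continuously at
  the requested status. Burst amplitude decays multiplicatively — with
  decay `d` per hour, the amplitude at minute `t` is `(1 − d)^(t/60)`
  of the start — emulating the intensity decline over long training;
  the per-bout amplitudes are stored as truth.

Default sampling rates are 500 Hz (ECG) and 1000 Hz (EMG), comfortably
resolving the ~100 ms QRS complex and the 20–450 Hz EMG band.

## The adaptive pressure controller and plant

The glove controller (`control_step`) is discrete proportional control:
the pressure command moves by `gain` (kPa/V) times the gap between the
intensity setpoint (default 1.5 V, the ECRL target) and the measured
segment RMS, clipped to the pump's 0–75 kPa range. On each
fatigue-confirmed step the command is additionally scaled by 0.8 and the
setpoint ramped down by 10%; at the default 0.2 s cadence a sustained
fatigue status therefore retires the assistance within seconds, which is
the intended protective endpoint. The simulated plant (`plant_step`)
is the minimal model able to reproduce both training regimes: a baseline
intensity decaying multiplicatively with time plus a linear assist term
(`assist_gain`, default 0.02 V/kPa) and Gaussian measurement noise.

With gain g, assist a, no noise and no decay, the closed loop is the
linear recurrence `P ← P + g(s − b − aP)`, which converges to the fixed
point `measured = s` whenever `g·a < 2`; the default `g·a = 0.5` leaves
a wide stability margin. The step cadence equals the EMG segment length
(`N/fs` = 0.2 s), so control and features share one clock.
`run_session` runs the loop for a whole session; with `adaptive = FALSE`
the pressure is held at its initial constant, giving the with/without
contrast: under 0.3/h decay over 60 min the open-loop intensity drops by
about 21% between the first and final third, while the closed loop holds
the final third within a few percent of the setpoint.

## Numerical and testing choices

* Problem sizes in the test-suite and acceptance script — 100 clean plus
  20 ambulatory ECG traces, 2,000–10,000 rule sequences, ~200 SVM windows
  per class, 20 four-motion scenes, 60-min control sessions at 0.2 s
  steps — are chosen to give stable percentages while keeping a full run
  in the low minutes on one core.
* Exactness claims (RMS vs brute force, normalization round-trip, R–R
  span conservation) are asserted at 1e−12 relative or better; span
  conservation is exact because sample times at 500 Hz lie on an exactly
  representable 2 ms grid.
* Clean-trace R-peak tests clamp generated intervals to ≥ 320 ms so the
  construction respects the detector's 300 ms refractory floor — at
  180 bpm with jitter an unconstrained draw can produce intervals no
  physiological detector should accept.
* The rule/SVM agreement check uses extreme regular vs irregular rhythms
  (jitter 0 vs 50 ms), where the two detectors must coincide.
* Ties in the rolling-majority smoother keep the raw label; ties in the
  dominance rule return `indeterminate` explicitly.

## Known limitations

* All quantitative performance figures are generator-conditional;
  nothing here validates against human recordings.
* The artifact filter targets spike-like transients; slow, large
  electrode-motion excursions are handled by the median baseline stage
  instead, and pathological combinations (artifact exactly mimicking a
  QRS) are not addressed.
* Frequency-domain HRV (LF/HF), arrhythmia handling, median-frequency
  EMG fatigue indices and per-motion (as opposed to per-group)
  classification are out of scope.
* The saturation regime of strong contractions (RMS_N > 0.95) is only
  flagged, not corrected.
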