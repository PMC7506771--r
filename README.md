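# rehabsig

Signal processing for wearable ECG/EMG monitoring during upper-limb
rehabilitation training, with a closed-loop simulation of an adaptive
pneumatic-glove pressure controller.

During glove-assisted hand training two signals matter: the
electrocardiogram (ECG), whose R–R interval regularity separates an
excited from a fatigued subject, and two-channel surface electromyogram
(EMG) over the flexor carpi radialis (FCR) and extensor carpi radialis
longus (ECRL), whose intensity tracks muscle effort and discriminates
flexion-type from extension-type hand motions. rehabsig is for engineers
and researchers building or evaluating such monitoring pipelines: it
provides the full processing chain, a seeded synthetic-signal generator
with exact ground truth so every stage is testable without hardware, and
the adaptive control loop that consumes the monitored signals.

## What it computes

* **ECG**: zero-phase 40 Hz low-pass → sliding-median baseline removal →
  adaptive artifact suppression → R-peak detection by the
  differential-threshold method (local maxima of the first difference,
  half-maximum amplitude threshold, minimum–R–R singularity removal) →
  R–R intervals → windowed HRV statistics. Per window of k = 10 beats:
  variation = max − min, mean R–R, SDNN = sd(RR), RMSSD =
  sqrt(mean(diff(RR)^2)).
* **Fatigue**: rule detector — fatigue when the variation of 10
  consecutive R–R measurements is below 5 ms — and a linear SVM on
  standardized (mean RR, SDNN, RMSSD, variation) features with a
  per-individual learning phase, majority-smoothed labels and alert
  events on excited→fatigue transitions.
* **EMG**: segment RMS = sqrt(sum(v_i^2)/N) with N = 200 samples;
  benchmark RMS_M = mean of three maximal-trial maxima; normalization
  RMS_N = RMS/RMS_M; activity segmentation (RMS_N ≥ 0.2 for ≥ 3
  segments); two-channel dominance rule — FCR > ECRL ⇒ forearm
  pronation / finger flexion group, ECRL > FCR ⇒ hand closing / wrist
  extension group.
* **Control**: discrete proportional pressure command
  P ← clip(P + g·(setpoint − RMS), 0, 75 kPa), attenuated ×0.8 with
  setpoint ramp-down on fatigue, exercised against a simulated plant
  (decaying baseline intensity + linear assist term + noise).

## Worked example

```r
library(rehabsig)

# 2 minutes of synthetic ambulatory ECG with known R peaks
rr <- gen_rr_series("excited", n = 150, mean_rr = 800, seed = 42)
g  <- gen_ecg(rr, fs = 500, noise = noise_preset("ambulatory"), seed = 43)
res <- process_ecg(g$signal)
res$peaks
#> <rpeak_series> 151 peaks  mean RR=799.1 ms (75.1 bpm)
head(res$hrv[, c("anchor_time", "variation", "mean_rr", "sdnn", "rmssd")], 3)
#>   anchor_time variation mean_rr     sdnn    rmssd
#> 1        8564        78   816.4 24.92299 43.02971
#> 2        9404        78   816.2 24.70178 40.59009
#> 3       10272        70   824.8 26.38518 40.59009
rule_fatigue(res$hrv)$flag
#> [1] FALSE
```

All 151 true beats are recovered (151 = 150 intervals + 1), the mean R–R
matches the generator's 800 ms, and the irregular (excited) rhythm keeps
every 10-beat variation far above the 5 ms fatigue threshold, so the rule
does not fire.

```r
# two-channel EMG: one flexion-type and one extension-type motion
m  <- gen_emg(data.frame(motion = c("finger_flexion", "hand_closing"),
                         onset_ms = c(1000, 7000), duration_ms = 3000),
              seed = 7)
detect_motion_events(m$fcr, m$ecrl,
                     calibration_record(2.0, "FCR"),
                     calibration_record(2.0, "ECRL"))
#>   onset_ms offset_ms fcr_rms_n ecrl_rms_n  motion_group
#> 1     1000      4000 0.9743151  0.4917451  fcr_dominant
#> 2     7000     10000 0.4912150  0.9414925 ecrl_dominant
```

Each burst yields one event; normalized intensities (~0.97 dominant vs
~0.49 non-dominant against the 2 V calibration) give the correct group.

```r
# 60-min adaptive session against a fatiguing plant (0.3/h decay)
run_session(TRUE, 60, plant_state(fatigue_decay = 0.3),
            control_state(setpoint = 1.5), seed = 42)
#> <session_trace> 18000 steps over 60.0 min
#>   mean measured RMS: first third 1.885 V, final third 1.520 V
#>   pressure range: [0.0, 9.6] kPa;  fatigue steps: 0
```

The controller holds the final-third intensity near the 1.5 V setpoint;
the same session with `adaptive = FALSE` decays to about 21% below its
starting intensity.

A command-line interface wrapping these functions is installed at
`inst/cli/rehabsig` (subcommands `simulate`, `process-ecg`,
`process-emg`, `classify`, `control-sim`, `run-all`).

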