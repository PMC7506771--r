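Package: rehabsig
Title: Wearable ECG/EMG Signal Processing and Adaptive Rehabilitation
    Control Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processing pipeline for wearable physiological monitoring
    during upper-limb rehabilitation training. Conditions single-channel
    electrocardiogram (ECG) traces (40 Hz low-pass, sliding-median
    baseline removal, adaptive artifact suppression), detects QRS R
    peaks by a differential-threshold method, extracts R-R intervals
    and windowed heart-rate-variability statistics, and classifies
    excited versus fatigue status by a threshold rule and a support
    vector machine. Extracts segment root-mean-square (RMS) features
    from two-channel surface electromyogram (EMG) recordings of the
    flexor carpi radialis and extensor carpi radialis longus,
    normalizes them against calibrated maximal contractions, segments
    activity bursts, and discriminates flexion-type from
    extension-type hand motions by channel dominance. Includes a
    seeded synthetic-signal generator with ground truth, and a
    closed-loop simulation of an adaptive pneumatic-glove pressure
    controller driven by the monitored signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
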