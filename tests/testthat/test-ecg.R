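test_that("lowpass_filter has unit DC gain, flat passband and strong stopband", {
  fs <- 500
  const <- sampled_signal(rep(0.7, 3000), fs = fs)
  out <- lowpass_filter(const, 40)
  mid <- 500:2500
  expect_lt(max(abs(out$samples[mid] - 0.7)), 1e-9)

  t <- (0:4999) / fs
  pass <- sampled_signal(sin(2 * pi * 5 * t), fs = fs)
  amp5 <- fit_sine_amplitude(lowpass_filter(pass, 40)$samples, fs, 5)
  expect_gt(amp5, 0.98)

  stopb <- sampled_signal(sin(2 * pi * 80 * t), fs = fs)
  amp80 <- fit_sine_amplitude(lowpass_filter(stopb, 40)$samples, fs, 80)
  expect_lt(amp80, 0.1)

  expect_error(lowpass_filter(pass, 250), class = "rehabsig_invalid_parameter")
})

test_that("remove_baseline_median flattens constants, ramps and slow wander", {
  fs <- 500
  const <- sampled_signal(rep(1.3, 2000), fs = fs)
  expect_lt(max(abs(remove_baseline_median(const)$samples)), 1e-12)

  ramp <- sampled_signal(seq(0, 1, length.out = 3000), fs = fs)
  out <- remove_baseline_median(ramp)
  interior <- 400:2600
  expect_lt(max(abs(out$samples[interior])), 1e-6)

  # clean ECG + 0.3 Hz wander: wander amplitude reduced by >= 80%
  rr <- gen_rr_series("excited", n = 60, mean_rr = 800, seed = 5)
  g <- gen_ecg(rr, fs = fs)
  t <- (seq_along(g$signal$samples) - 1) / fs
  wander <- 0.1 * sin(2 * pi * 0.3 * t)
  noisy <- sampled_signal(g$signal$samples + wander, fs = fs)
  resid <- remove_baseline_median(noisy)
  amp_after <- fit_sine_amplitude(resid$samples - g$signal$samples, fs, 0.3,
                                  trim_s = 1)
  expect_lt(amp_after, 0.2 * 0.1)

  expect_error(remove_baseline_median(const, window = 1),
               class = "rehabsig_invalid_parameter")
})

test_that("sliding median used for baseline equals a brute-force sort oracle", {
  set.seed(42)
  v <- rnorm(500)
  for (k in c(5, 31, 101)) {
    sig <- sampled_signal(v, fs = 1000)
    out <- remove_baseline_median(sig, window = k)
    expect_equal(v - out$samples, brute_sliding_median(v, k), tolerance = 1e-12)
  }
})

test_that("suppress_artifacts leaves clean traces untouched and removes spikes", {
  rr <- gen_rr_series("excited", n = 40, mean_rr = 800, seed = 3)
  g <- gen_ecg(rr, fs = 500)
  cond <- remove_baseline_median(lowpass_filter(g$signal))
  expect_identical(suppress_artifacts(cond)$samples, cond$samples)

  # single large spike: replaced, distant samples unchanged
  v <- cond$samples
  i <- 5000L
  v[i] <- v[i] + 10
  spiked <- sampled_signal(v, fs = 500)
  fixed <- suppress_artifacts(spiked)
  expect_lt(abs(fixed$samples[i] - cond$samples[i]), 0.5)
  far <- setdiff(seq_along(v), (i - 20):(i + 20))
  expect_equal(fixed$samples[far], cond$samples[far])

  # constant signal passes through
  const <- sampled_signal(rep(2, 1000), fs = 500)
  expect_identical(suppress_artifacts(const)$samples, const$samples)
})

test_that("artifact suppression does not hurt R-peak detection on corrupted traces", {
  noise <- noise_spec(motion_artifact_rate = 8, motion_artifact_amp = 2,
                      white_noise_sd = 0.03)
  f1 <- function(m) 2 * m$tp / (2 * m$tp + (1 / m$recall - 1) * m$tp +
                                  (1 / m$precision - 1) * m$tp)
  better <- 0L
  for (s in 1:5) {
    rr <- gen_rr_series("excited", n = 100, mean_rr = 750, seed = s)
    g <- gen_ecg(rr, fs = 500, noise = noise, seed = s + 30)
    with_f <- process_ecg(g$signal, artifact_filter = TRUE)
    without <- process_ecg(g$signal, artifact_filter = FALSE)
    mf <- match_peaks(with_f$peaks$peak_times, g$truth$r_peak_times, 20)
    mo <- match_peaks(without$peaks$peak_times, g$truth$r_peak_times, 20)
    expect_gte(f1(mf), f1(mo) - 1e-12)
  }
})

test_that("detect_r_peaks recovers clean constructions and rejects bad input", {
  g <- gen_ecg(c(1000, 1000, 1000), fs = 500)
  cond <- remove_baseline_median(lowpass_filter(g$signal))
  pk <- detect_r_peaks(cond)
  expect_length(pk$peak_times, 4)
  expect_true(all(abs(pk$peak_times - g$truth$r_peak_times) <= 1000 / 500))

  flat <- sampled_signal(rep(0, 2500), fs = 500)
  expect_length(detect_r_peaks(flat)$peak_times, 0)

  short <- sampled_signal(rep(0, 100), fs = 500)
  expect_error(detect_r_peaks(short), class = "rehabsig_invalid_input")
})

test_that("detected peaks always satisfy the series invariants", {
  for (s in 1:8) {
    bpm <- 40 + (s - 1) * 20
    rr <- gen_rr_series("excited", n = 40, mean_rr = 60000 / bpm,
                        jitter_sd = min(30, 60000 / bpm / 10), seed = s)
    g <- gen_ecg(rr, fs = 500, noise = noise_preset("ambulatory"), seed = s)
    pk <- process_ecg(g$signal)$peaks
    expect_true(all(diff(pk$peak_times) > 0))
    expect_true(all(diff(pk$peak_times) >= 300))
  }
})

test_that("compute_rr differences peak times and conserves the span", {
  pk <- structure(list(peak_times = c(0, 1000, 2000, 3000),
                       peak_indices = 1:4, peak_amplitudes = rep(1, 4),
                       fs = 500), class = "rpeak_series")
  expect_equal(compute_rr(pk)$intervals, c(1000, 1000, 1000))

  pk$peak_times <- c(0, 800, 1900)
  expect_equal(compute_rr(pk)$intervals, c(800, 1100))

  set.seed(1)
  tms <- cumsum(runif(50, 300, 1500))
  pk$peak_times <- tms
  rr <- compute_rr(pk)
  expect_equal(sum(rr$intervals), tms[50] - tms[1])

  pk$peak_times <- 100
  expect_error(compute_rr(pk), class = "rehabsig_insufficient_data")
})

test_that("hrv_windows matches direct recomputation and the worked example", {
  h <- hrv_windows(rr_series(c(101, 80, 113)), k = 3)
  expect_equal(nrow(h), 1)
  expect_equal(h$variation, 33)

  h0 <- hrv_windows(rr_series(rep(900, 10)), k = 10)
  expect_equal(h0$variation, 0)
  expect_equal(h0$sdnn, 0)
  expect_equal(h0$rmssd, 0)

  set.seed(7)
  v <- runif(40, 600, 1000)
  h <- hrv_windows(rr_series(v), k = 10)
  expect_equal(nrow(h), 31)  # len - k + 1
  for (i in c(1, 15, 31)) {
    w <- v[i:(i + 9)]
    expect_equal(h$variation[i], max(w) - min(w))
    expect_equal(h$mean_rr[i], mean(w))
    expect_equal(h$sdnn[i], sd(w))
    expect_equal(h$rmssd[i], sqrt(mean(diff(w)^2)))
  }

  expect_error(hrv_windows(rr_series(c(800, 810)), k = 10),
               class = "rehabsig_insufficient_data")
})

test_that("baseline removal is idempotent on centered input", {
  const <- sampled_signal(rep(0.5, 2000), fs = 500)
  once <- remove_baseline_median(const)
  twice <- remove_baseline_median(once)
  expect_lt(max(abs(twice$samples - once$samples)), 1e-9)
})

test_that("mark_waves annotates P/Q/S/T around each R", {
  g <- gen_ecg(rep(900, 5), fs = 500)
  cond <- remove_baseline_median(lowpass_filter(g$signal))
  pk <- detect_r_peaks(cond)
  ann <- mark_waves(cond, pk)
  expect_equal(nrow(ann), 6)
  # template geometry: Q before R before S; P before Q; T after S
  expect_true(all(ann$Q < ann$R & ann$R < ann$S))
  expect_true(all(ann$P < ann$Q & ann$T > ann$S))
  # T offset ~250 ms, P offset ~180 ms from R
  expect_true(all(abs(ann$T - ann$R - 250) < 40))
  expect_true(all(abs(ann$R - ann$P - 180) < 40))
})
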