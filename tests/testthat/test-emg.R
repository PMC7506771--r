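test_that("rectify takes absolute values and is idempotent", {
  s <- sampled_signal(c(-1, 2, -3), fs = 1000, channel = "FCR")
  expect_equal(rectify(s)$samples, c(1, 2, 3))
  nn <- sampled_signal(c(0, 1, 2), fs = 1000, channel = "FCR")
  expect_equal(rectify(nn)$samples, nn$samples)
  expect_equal(rectify(rectify(s))$samples, rectify(s)$samples)
})

test_that("rms_segments matches the direct-sum oracle and simple cases", {
  const <- sampled_signal(rep(2, 1000), fs = 1000, channel = "FCR")
  expect_equal(rms_segments(const)$rms, rep(2, 5))

  alt <- sampled_signal(rep(c(1, -1), 300), fs = 1000, channel = "FCR")
  expect_equal(rms_segments(alt)$rms, rep(1, 3))

  set.seed(11)
  v <- rnorm(1000)
  got <- rms_segments(sampled_signal(v, fs = 1000, channel = "FCR"))$rms
  want <- vapply(1:5, function(i) {
    seg <- v[((i - 1) * 200 + 1):(i * 200)]
    sqrt(sum(seg^2) / 200)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  # trailing remainder dropped
  expect_equal(nrow(rms_segments(sampled_signal(rnorm(450), 1000,
                                                channel = "FCR"))), 2)
  expect_error(rms_segments(sampled_signal(rnorm(100), 1000, channel = "FCR")),
               class = "rehabsig_insufficient_data")
})

test_that("rms_segments is scale-equivariant", {
  set.seed(12)
  v <- rnorm(800)
  base <- rms_segments(sampled_signal(v, 1000, channel = "FCR"))$rms
  for (a in c(0.5, 3, 100)) {
    scaled <- rms_segments(sampled_signal(a * v, 1000, channel = "FCR"))$rms
    expect_equal(scaled, a * base, tolerance = 1e-12)
  }
})

test_that("calibration averages the three maximal-trial maxima", {
  mk <- function(level) sampled_signal(rep(level, 400), fs = 1000,
                                       channel = "FCR")
  cal <- calibrate_rms_max(list(mk(2.0), mk(2.2), mk(1.8)))
  expect_equal(cal$rms_m, 2.0)
  expect_equal(cal$trial_rms, c(2.0, 2.2, 1.8))

  cal_same <- calibrate_rms_max(list(mk(1.5), mk(1.5), mk(1.5)))
  expect_equal(cal_same$rms_m, 1.5)

  expect_error(calibrate_rms_max(list()), class = "rehabsig_invalid_input")
})

test_that("generator maximal trials calibrate near the configured maximum", {
  trials <- lapply(1:3, function(s) {
    g <- gen_emg(data.frame(motion = "finger_flexion", onset_ms = 200,
                            duration_ms = 1500), seed = s,
                 duration_ms = 2000, burst_rms = 2.0)
    g$fcr
  })
  cal <- calibrate_rms_max(trials)
  expect_lt(abs(cal$rms_m - 2.0) / 2.0, 0.1)
})

test_that("normalization divides by RMS_M and round-trips exactly", {
  s <- sampled_signal(rep(1.5, 600), fs = 1000, channel = "FCR")
  feats <- rms_segments(s)
  cal <- calibration_record(1.5, "FCR")
  nf <- normalize_rms(feats, cal)
  expect_equal(nf$rms_normalized, rep(1, 3))

  z <- rms_segments(sampled_signal(rep(0, 400), 1000, channel = "FCR"))
  expect_equal(normalize_rms(z, cal)$rms_normalized, c(0, 0))

  set.seed(13)
  feats <- rms_segments(sampled_signal(rnorm(2000, sd = 0.5), 1000,
                                       channel = "FCR"))
  cal <- calibration_record(c(1.9, 2.1, 2.0), "FCR")
  nf <- normalize_rms(feats, cal)
  expect_equal(nf$rms_normalized * cal$rms_m, feats$rms, tolerance = 1e-12)

  bad_cal <- structure(list(channel = "FCR", trial_rms = 1, rms_m = 0),
                       class = "calibration_record")
  expect_error(normalize_rms(feats, bad_cal),
               class = "rehabsig_invalid_calibration")
  expect_error(calibration_record(c(2, -1, 2)),
               class = "rehabsig_invalid_parameter")
})

test_that("segment_activity finds bursts, merges blips and needs normalization", {
  cal <- calibration_record(2.0, "FCR")

  base <- gen_emg(data.frame(motion = character(0), onset_ms = numeric(0),
                             duration_ms = numeric(0)), seed = 1)
  nf <- normalize_rms(rms_segments(base$fcr), cal)
  expect_equal(nrow(segment_activity(nf)), 0)

  g <- gen_emg(data.frame(motion = "finger_flexion", onset_ms = 2000,
                          duration_ms = 3000), seed = 2)
  nf <- normalize_rms(rms_segments(g$fcr), cal)
  ev <- segment_activity(nf)
  expect_equal(nrow(ev), 1)
  overlap <- min(ev$offset_ms, 5000) - max(ev$onset_ms, 2000)
  expect_gte(overlap / 3000, 0.8)

  two <- gen_emg(data.frame(motion = c("finger_flexion", "finger_flexion"),
                            onset_ms = c(1000, 8000), duration_ms = 2000),
                 seed = 3)
  nf2 <- normalize_rms(rms_segments(two$fcr), cal)
  ev2 <- segment_activity(nf2)
  expect_equal(nrow(ev2), 2)
  expect_lt(ev2$onset_ms[1], ev2$onset_ms[2])

  expect_error(segment_activity(rms_segments(g$fcr)),
               class = "rehabsig_invalid_input")
})

test_that("a single sub-threshold dip does not split a contraction", {
  vals <- c(0.05, 0.5, 0.6, 0.1, 0.55, 0.5, 0.05)
  df <- data.frame(segment = seq_along(vals),
                   start_ms = (seq_along(vals) - 1) * 200,
                   rms = vals * 2, rms_normalized = vals)
  attr(df, "N") <- 200L; attr(df, "fs") <- 1000
  class(df) <- c("emg_features", "data.frame")
  ev <- segment_activity(df, threshold = 0.2, min_duration = 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_segments, 5)
})

test_that("classify_motion applies the dominance rule", {
  expect_equal(classify_motion(1.5, 0.8), "fcr_dominant")
  expect_equal(classify_motion(0.8, 1.5), "ecrl_dominant")
  expect_equal(classify_motion(1.0, 1.0), "indeterminate")
  expect_error(classify_motion(0.05, 0.1), class = "rehabsig_no_activity")
})

test_that("every truth motion window yields one event with correct dominance", {
  cal_f <- calibration_record(2.0, "FCR")
  cal_e <- calibration_record(2.0, "ECRL")
  for (s in 1:5) {
    g <- four_motion_scene(seed = 200 + s)
    ev <- detect_motion_events(g$fcr, g$ecrl, cal_f, cal_e)
    expect_equal(nrow(ev), 4)
    for (i in 1:4) {
      hit <- which(ev$onset_ms < g$truth$offset_ms[i] &
                   ev$offset_ms > g$truth$onset_ms[i])
      expect_length(hit, 1)
      expect_equal(ev$dominant_channel[hit], g$truth$dominant[i])
    }
  }
})

test_that("event peak RMS grows with envelope amplitude below saturation", {
  cal_f <- calibration_record(2.0, "FCR")
  cal_e <- calibration_record(2.0, "ECRL")
  peaks <- vapply(c(0.8, 1.2, 1.6), function(a) {
    g <- gen_emg(data.frame(motion = "finger_flexion", onset_ms = 1000,
                            duration_ms = 3000), seed = 9, burst_rms = a)
    ev <- detect_motion_events(g$fcr, g$ecrl, cal_f, cal_e)
    ev$peak_rms_n[1]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
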