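test_that("gen_rr_series is reproducible and respects status regularity", {
  a <- gen_rr_series("excited", n = 100, mean_rr = 800, seed = 11)
  b <- gen_rr_series("excited", n = 100, mean_rr = 800, seed = 11)
  expect_identical(a, b)

  # fatigue: every sliding 10-window has range < 5 ms, exhaustively
  for (s in 1:5) {
    rr <- gen_rr_series("fatigue", n = 100, mean_rr = 900, seed = s)
    expect_length(rr, 100)
    expect_true(all(rr > 0))
    rng <- vapply(1:91, function(i) max(rr[i:(i + 9)]) - min(rr[i:(i + 9)]),
                  numeric(1))
    expect_true(all(rng < 5))
  }

  # excited: every 10-window range >= 5 ms
  for (s in 1:5) {
    rr <- gen_rr_series("excited", n = 100, mean_rr = 800, seed = s)
    rng <- vapply(1:91, function(i) max(rr[i:(i + 9)]) - min(rr[i:(i + 9)]),
                  numeric(1))
    expect_true(all(rng >= 5))
  }

  # zero jitter: exactly the mean
  expect_equal(gen_rr_series("fatigue", n = 10, mean_rr = 900, jitter_sd = 0),
               rep(900, 10))

  # large-sample spread close to the configured jitter SD
  rr <- gen_rr_series("excited", n = 1000, mean_rr = 800, seed = 7)
  expect_gt(sd(rr), 30 / 3)
  expect_lt(sd(rr), 30 * 3)
})

test_that("gen_rr_series rejects invalid parameters", {
  expect_error(gen_rr_series("excited", n = 1), class = "rehabsig_invalid_parameter")
  expect_error(gen_rr_series("excited", n = 10, mean_rr = 100),
               class = "rehabsig_invalid_parameter")
  expect_error(gen_rr_series("excited", n = 10, mean_rr = 2500),
               class = "rehabsig_invalid_parameter")
})

test_that("gen_ecg places one R apex per beat at the stored truth times", {
  g <- gen_ecg(c(1000, 1000, 1000), fs = 500)
  expect_length(g$truth$r_peak_times, 4)
  expect_equal(diff(g$truth$r_peak_times), rep(1000, 3))

  # per-beat maximum lies within 1 sample of the truth R time
  for (s in 1:10) {
    rr <- gen_rr_series("excited", n = 20, mean_rr = 700, seed = s)
    g <- gen_ecg(rr, fs = 500, seed = s)
    t_ms <- signal_times(g$signal)
    expect_length(g$truth$r_peak_times, length(rr) + 1)
    for (rt in g$truth$r_peak_times) {
      win <- which(abs(t_ms - rt) <= 150)
      apex <- t_ms[win][which.max(g$signal$samples[win])]
      expect_lte(abs(apex - rt), 1000 / 500)
    }
  }

  expect_error(gen_ecg(c(800, 800), fs = 100),
               class = "rehabsig_invalid_parameter")
  expect_error(gen_ecg(c(800, -5), fs = 500),
               class = "rehabsig_invalid_parameter")
})

test_that("gen_emg enforces channel dominance inside every motion window", {
  win_rms <- function(sig, on, off) {
    t <- signal_times(sig)
    v <- sig$samples[t >= on & t < off]
    sqrt(mean(v^2))
  }
  for (s in 1:5) {
    g <- four_motion_scene(seed = s)
    for (i in seq_len(nrow(g$truth))) {
      # measure the plateau (skip the 100 ms ramps)
      on <- g$truth$onset_ms[i] + 200
      off <- g$truth$offset_ms[i] - 200
      f <- win_rms(g$fcr, on, off)
      e <- win_rms(g$ecrl, on, off)
      if (g$truth$dominant[i] == "FCR") {
        expect_gt(f, 1.2 * e)
      } else {
        expect_gt(e, 1.2 * f)
      }
    }
  }
})

test_that("gen_emg with no motions yields sub-threshold baseline only", {
  g <- gen_emg(data.frame(motion = character(0), onset_ms = numeric(0),
                          duration_ms = numeric(0)), seed = 2)
  cal <- calibration_record(2.0, "FCR")
  f <- normalize_rms(rms_segments(g$fcr), cal)
  expect_true(all(f$rms_normalized < 0.2))
})

test_that("gen_emg rejects overlapping windows and unknown labels", {
  bad <- data.frame(motion = c("finger_flexion", "hand_closing"),
                    onset_ms = c(0, 500), duration_ms = c(1000, 1000))
  expect_error(gen_emg(bad, seed = 1), class = "rehabsig_invalid_parameter")
  expect_error(gen_emg(data.frame(motion = "fist_bump", onset_ms = 0,
                                  duration_ms = 1000), seed = 1),
               class = "rehabsig_invalid_parameter")
})

test_that("a generated motion burst round-trips through motion classification", {
  g <- gen_emg(data.frame(motion = "wrist_extension", onset_ms = 1000,
                          duration_ms = 3000), seed = 4)
  cal <- calibration_record(2.0, "FCR")
  cal_e <- calibration_record(2.0, "ECRL")
  ev <- detect_motion_events(g$fcr, g$ecrl, cal, cal_e)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$motion_group, "ecrl_dominant")
})

test_that("gen_session burst amplitude decays at the configured rate", {
  ses <- gen_session("excited", duration_min = 3, decay = 0.5, seed = 6)
  bm <- ses$truth$bout_means
  expect_equal(nrow(bm), 3)
  # (1-d)^(1/60) per minute, exactly, in the stored truth
  expect_equal(bm$ecrl_mean_amp[2] / bm$ecrl_mean_amp[1], 0.5^(1 / 60))
  expect_lt(bm$ecrl_mean_amp[3], bm$ecrl_mean_amp[1])

  # decay 0: bout means equal
  ses0 <- gen_session("excited", duration_min = 2, decay = 0, seed = 6)
  bm0 <- ses0$truth$bout_means
  expect_equal(bm0$fcr_mean_amp[1], bm0$fcr_mean_amp[2])
})

test_that("measured session EMG reflects the truth decay direction", {
  ses <- gen_session("excited", duration_min = 3, decay = 0.9, seed = 8)
  cal <- calibration_record(2.0, "FCR")
  f <- normalize_rms(rms_segments(ses$fcr), cal)
  ev <- segment_activity(f)
  minute <- floor(f$start_ms / 60000)
  active <- vapply(f$start_ms, function(s)
    any(s >= ev$onset_ms & s < ev$offset_ms), logical(1))
  m_first <- mean(f$rms[active & minute == 0])
  m_last <- mean(f$rms[active & minute == 2])
  expect_lt(m_last, m_first)
})

test_that("fatigue-status session triggers the rule within two minutes", {
  ses <- gen_session("fatigue", duration_min = 2, decay = 0.2, seed = 3)
  pr <- process_ecg(ses$ecg)
  r <- rule_fatigue(pr$hrv)
  expect_true(r$flag)
  expect_lt(pr$hrv$anchor_time[r$first_trigger_index], 120000)
})
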