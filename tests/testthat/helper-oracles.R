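# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Greedy peak matcher: one detected peak per truth peak within tolerance.
match_peaks <- function(detected, truth, tol_ms) {
  used <- logical(length(detected))
  tp <- 0L
  for (t in truth) {
    if (!length(detected)) break
    d <- abs(detected - t)
    i <- which.min(d)
    if (d[i] <= tol_ms && !used[i]) {
      used[i] <- TRUE
      tp <- tp + 1L
    }
  }
  list(recall = tp / length(truth),
       precision = if (length(detected)) tp / length(detected) else NA_real_,
       tp = tp)
}

# Brute-force sliding median with reflection padding (sort-based).
brute_sliding_median <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  pad <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  vapply(seq_len(n), function(i) {
    sort(pad[i:(i + k - 1L)])[h + 1L]
  }, numeric(1))
}

# Least-squares sinusoid amplitude at a known frequency.
fit_sine_amplitude <- function(x, fs, freq, trim_s = 0.5) {
  n <- length(x)
  i <- seq_len(n)
  keep <- i > trim_s * fs & i <= n - trim_s * fs
  t <- (i[keep] - 1) / fs
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  b <- stats::coef(stats::lm.fit(X, x[keep]))
  sqrt(sum(b^2))
}

# hrv_windows object with prescribed variation values (other stats zeroed),
# for rule-level tests that do not need real intervals.
fake_hrv <- function(variation, k = 10) {
  out <- data.frame(start = seq_along(variation),
                    anchor_time = seq_along(variation) * 1000,
                    variation = variation,
                    mean_rr = 900, sdnn = 0, rmssd = 0)
  attr(out, "window_size") <- as.integer(k)
  class(out) <- c("hrv_windows", "data.frame")
  out
}

# Balanced labelled HRV feature set from the generator, for SVM tests.
make_status_features <- function(n_series, n_int = 60, seed0 = 0) {
  fe <- do.call(rbind, lapply(seq_len(n_series), function(s) {
    extract_features(rr_series(
      gen_rr_series("excited", n_int, 800, seed = seed0 + s)))
  }))
  ff <- do.call(rbind, lapply(seq_len(n_series), function(s) {
    extract_features(rr_series(
      gen_rr_series("fatigue", n_int, 900, seed = seed0 + 1000 + s)))
  }))
  list(x = rbind(fe, ff),
       y = rep(c("excited", "fatigue"), c(nrow(fe), nrow(ff))))
}

four_motion_scene <- function(seed, gap_ms = 3000, dur_ms = 3000) {
  motions <- data.frame(
    motion = c("hand_closing", "forearm_pronation",
               "finger_flexion", "wrist_extension"),
    onset_ms = 1000 + (0:3) * (dur_ms + gap_ms),
    duration_ms = dur_ms)
  gen_emg(motions, seed = seed)
}
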