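#' Noise model for synthetic ECG
#'
#' Describes the additive disturbances applied to a clean synthetic ECG
#' trace: sinusoidal baseline wander (respiration-scale drift), 50 Hz
#' powerline pickup, short motion-artifact spikes from transient
#' electrode-contact loss, and broadband white noise.
#'
#' @param baseline_wander_amp wander amplitude (V).
#' @param baseline_wander_freq wander frequency (Hz).
#' @param powerline_amp 50 Hz interference amplitude (V).
#' @param motion_artifact_rate artifact events per minute.
#' @param motion_artifact_amp artifact spike amplitude (V).
#' @param white_noise_sd white-noise standard deviation (V).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_wander_amp = 0, baseline_wander_freq = 0.3,
                       powerline_amp = 0, motion_artifact_rate = 0,
                       motion_artifact_amp = 2, white_noise_sd = 0) {
  amps <- c(baseline_wander_amp, powerline_amp, motion_artifact_amp,
            white_noise_sd, motion_artifact_rate)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop_invalid_parameter("noise amplitudes and rates must be finite and >= 0")
  }
  structure(list(baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq = baseline_wander_freq,
                 powerline_amp = powerline_amp,
                 motion_artifact_rate = motion_artifact_rate,
                 motion_artifact_amp = motion_artifact_amp,
                 white_noise_sd = white_noise_sd),
            class = "noise_spec")
}

#' Named noise presets
#'
#' `"clean"` is noise-free; `"ambulatory"` emulates recording during
#' movement: 0.2 V baseline wander at 0.3 Hz, 0.05 V powerline pickup,
#' 4 motion-artifact spikes per minute of 2 V, and 0.03 V white noise.
#'
#' @param preset `"clean"` or `"ambulatory"`.
#' @return A [noise_spec].
#' @export
noise_preset <- function(preset = c("clean", "ambulatory")) {
  preset <- match.arg(preset)
  switch(preset,
    clean = noise_spec(),
    ambulatory = noise_spec(baseline_wander_amp = 0.2,
                            baseline_wander_freq = 0.3,
                            powerline_amp = 0.05,
                            motion_artifact_rate = 4,
                            motion_artifact_amp = 2,
                            white_noise_sd = 0.03)
  )
}

#' Generate an R-R interval series for a physiological status
#'
#' Heartbeat-interval sequences differ between the two monitored states:
#' in the excited state the R-R series is irregular (large beat-to-beat
#' jitter), while fatigue shows a near-regular rhythm. Intervals are
#' drawn as `mean_rr` plus Gaussian jitter. For `status = "fatigue"` the
#' jitter is rejection-resampled to stay within +/- 2.45 ms of the mean so
#' that every window of 10 consecutive intervals has range < 5 ms — the
#' regularity that triggers the fatigue rule — by construction. For
#' `status = "excited"` any 10-interval window whose range falls below
#' 5 ms is redrawn, so the rule never fires on an excited series.
#'
#' @param status `"excited"` or `"fatigue"`.
#' @param n number of intervals (>= 2).
#' @param mean_rr mean R-R interval in ms, within \[300, 2000\].
#' @param jitter_sd jitter standard deviation (ms); defaults to 30 ms for
#'   excited, 1 ms for fatigue.
#' @param seed RNG seed (optional but recommended for reproducibility).
#' @return Numeric vector of `n` positive intervals (ms).
#' @examples
#' gen_rr_series("fatigue", n = 10, mean_rr = 900, seed = 1)
#' @export
gen_rr_series <- function(status = c("excited", "fatigue"), n, mean_rr = NULL,
                          jitter_sd = NULL, seed = NULL) {
  status <- match.arg(status)
  if (!is_count(n, min = 2L)) {
    stop_invalid_parameter("n must be an integer >= 2")
  }
  if (is.null(mean_rr)) mean_rr <- if (status == "excited") 800 else 900
  if (!is_scalar_num(mean_rr) || mean_rr < 300 || mean_rr > 2000) {
    stop_invalid_parameter("mean_rr must be in [300, 2000] ms")
  }
  if (is.null(jitter_sd)) jitter_sd <- if (status == "excited") 30 else 1
  if (!is_scalar_num(jitter_sd) || jitter_sd < 0) {
    stop_invalid_parameter("jitter_sd must be >= 0")
  }

  with_rng_seed(seed, {
    if (status == "fatigue") {
      # Jitter truncated to +/-2.45 ms => any window range <= 4.9 < 5 ms.
      lim <- min(2.45, mean_rr - 1)
      j <- stats::rnorm(n, 0, jitter_sd)
      if (jitter_sd > 0) {
        for (iter in 1:100) {
          bad <- which(abs(j) > lim)
          if (!length(bad)) break
          j[bad] <- stats::rnorm(length(bad), 0, jitter_sd)
        }
        j[abs(j) > lim] <- 0
      }
      rr <- mean_rr + j
    } else {
      rr <- draw_positive(n, mean_rr, jitter_sd)
      if (n >= 10L && jitter_sd > 0) {
        # Redraw any too-regular 10-interval window.
        for (iter in 1:200) {
          rng <- window_ranges(rr, 10L)
          bad <- which(rng < 5)
          if (!length(bad)) break
          idx <- unique(unlist(lapply(bad, function(i) i:(i + 9L))))
          rr[idx] <- draw_positive(length(idx), mean_rr, jitter_sd)
        }
      }
    }
    rr
  })
}

# Gaussian draws truncated (by redraw) to stay positive.
draw_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- which(x <= 0)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  x[x <= 0] <- mean
  x
}

# max - min over each sliding window of k values.
window_ranges <- function(x, k) {
  n <- length(x)
  if (n < k) return(numeric(0))
  vapply(seq_len(n - k + 1L), function(i) {
    w <- x[i:(i + k - 1L)]
    max(w) - min(w)
  }, numeric(1))
}

# PQRST template parameters: Gaussian bumps at offsets (ms) from the R
# apex, with amplitudes (V, R normalized to 1) and widths (ms).
pqrst_waves <- function() {
  data.frame(wave   = c("P", "Q", "R", "S", "T"),
             offset = c(-180, -35, 0, 35, 250),
             amp    = c(0.15, -0.10, 1.00, -0.20, 0.30),
             sigma  = c(25, 10, 12, 10, 60))
}

#' Generate a synthetic ECG trace with ground truth
#'
#' Builds one PQRST complex per heartbeat as a sum of five Gaussian bumps
#' (P, Q, R, S, T), with the R bump the per-beat maximum, places the beats
#' at the cumulative R-R interval times, and adds noise per the
#' [noise_spec]. The true R-apex times are returned as ground truth, so
#' detector accuracy can be scored exactly.
#'
#' @param rr_intervals vector of R-R intervals (ms), e.g. from
#'   [gen_rr_series()]. `k` intervals produce `k + 1` beats.
#' @param fs sampling rate (Hz); must be >= 200 so the ~100 ms QRS complex
#'   is resolvable.
#' @param noise a [noise_spec]; default clean.
#' @param seed RNG seed for the noise.
#' @param r_amp R-wave amplitude (V).
#' @return A list with elements `signal` (a [sampled_signal]) and `truth`
#'   (list with `r_peak_times` ms, `rr_intervals` ms).
#' @examples
#' ecg <- gen_ecg(c(1000, 1000, 1000), fs = 500)
#' length(ecg$truth$r_peak_times)  # 4 beats
#' @export
gen_ecg <- function(rr_intervals, fs = 500, noise = noise_spec(), seed = NULL,
                    r_amp = 1.0) {
  if (!is.numeric(rr_intervals) || length(rr_intervals) < 1L ||
      any(!is.finite(rr_intervals)) || any(rr_intervals <= 0)) {
    stop_invalid_parameter("rr_intervals must be positive and finite")
  }
  if (!is_scalar_num(fs) || fs < 200) {
    stop_invalid_parameter("fs must be >= 200 Hz to resolve the QRS complex")
  }
  stopifnot(inherits(noise, "noise_spec"))

  lead_ms <- 400   # room for the first P wave
  tail_ms <- 450   # room for the last T wave
  r_times <- lead_ms + cumsum(c(0, rr_intervals))
  total_ms <- r_times[length(r_times)] + tail_ms
  n <- ceiling(total_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs

  waves <- pqrst_waves()
  waves$amp <- waves$amp * r_amp
  x <- numeric(n)
  for (rt in r_times) {
    for (w in seq_len(nrow(waves))) {
      mu <- rt + waves$offset[w]
      sig <- waves$sigma[w]
      # only evaluate within +/- 5 sigma
      i0 <- max(1L, floor((mu - 5 * sig) * fs / 1000) + 1L)
      i1 <- min(n, ceiling((mu + 5 * sig) * fs / 1000) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      x[idx] <- x[idx] + waves$amp[w] * exp(-((t_ms[idx] - mu) / sig)^2 / 2)
    }
  }

  x <- with_rng_seed(seed, x + render_noise(n, fs, t_ms, noise))

  list(signal = sampled_signal(x, fs = fs, channel = "ECG"),
       truth = list(r_peak_times = r_times, rr_intervals = as.numeric(rr_intervals)))
}

# Additive noise realization per the spec; call inside with_rng_seed.
render_noise <- function(n, fs, t_ms, noise) {
  z <- numeric(n)
  if (noise$baseline_wander_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    z <- z + noise$baseline_wander_amp *
      sin(2 * pi * noise$baseline_wander_freq * t_ms / 1000 + phase)
  }
  if (noise$powerline_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    z <- z + noise$powerline_amp * sin(2 * pi * 50 * t_ms / 1000 + phase)
  }
  if (noise$white_noise_sd > 0) {
    z <- z + stats::rnorm(n, 0, noise$white_noise_sd)
  }
  if (noise$motion_artifact_rate > 0 && noise$motion_artifact_amp > 0) {
    dur_min <- n / fs / 60
    k <- stats::rpois(1, noise$motion_artifact_rate * dur_min)
    if (k > 0) {
      at <- sort(stats::runif(k, 0, n / fs * 1000))
      for (a in at) {
        # short spike: 2-10 ms of elevated contact transient
        wid_ms <- stats::runif(1, 2, 10)
        i0 <- max(1L, round(a * fs / 1000))
        i1 <- min(n, i0 + max(1L, round(wid_ms * fs / 1000)))
        amp <- noise$motion_artifact_amp * sample(c(-1, 1), 1)
        z[i0:i1] <- z[i0:i1] + amp
      }
    }
  }
  z
}

motion_labels <- c("hand_closing", "forearm_pronation",
                   "finger_flexion", "wrist_extension")
fcr_dominant_motions  <- c("forearm_pronation", "finger_flexion")
ecrl_dominant_motions <- c("hand_closing", "wrist_extension")

#' Generate two-channel synthetic surface EMG with ground truth
#'
#' Each channel is band-limited (20-450 Hz) white noise of unit RMS,
#' amplitude-modulated by a trapezoidal envelope inside each motion
#' window and held at a small baseline outside. Channel dominance follows
#' the physiology of the two forearm muscles: forearm pronation and
#' finger flexion activate the FCR more strongly than the ECRL; hand
#' closing and wrist extension activate the ECRL more strongly.
#'
#' @param motions data.frame with columns `motion` (one of `hand_closing`,
#'   `forearm_pronation`, `finger_flexion`, `wrist_extension`), `onset_ms`,
#'   `duration_ms`. Windows must not overlap. May have zero rows (pure
#'   baseline).
#' @param fs sampling rate (Hz), default 1000.
#' @param seed RNG seed.
#' @param duration_ms total trace length; defaults to last offset + 1000 ms.
#' @param burst_rms target RMS (V) of the dominant channel inside a burst.
#' @param dominance_ratio dominant / non-dominant RMS ratio (>= 1.2).
#' @param baseline_rms resting-activity RMS (V).
#' @param ramp_ms rise/fall time of the trapezoidal envelope.
#' @return List with `fcr`, `ecrl` ([sampled_signal]s) and `truth`
#'   (the motion windows plus the per-window envelope amplitudes used).
#' @export
gen_emg <- function(motions, fs = 1000, seed = NULL, duration_ms = NULL,
                    burst_rms = 2.0, dominance_ratio = 2.0,
                    baseline_rms = 0.1, ramp_ms = 100) {
  motions <- validate_motions(motions)
  if (dominance_ratio < 1.2) {
    stop_invalid_parameter("dominance_ratio must be >= 1.2")
  }
  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(motions)) {
      max(motions$onset_ms + motions$duration_ms) + 1000
    } else 10000
  }
  n <- ceiling(duration_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs

  with_rng_seed(seed, {
    env_f <- rep(baseline_rms, n)
    env_e <- rep(baseline_rms, n)
    amps <- data.frame(motion = character(0), fcr_amp = numeric(0),
                       ecrl_amp = numeric(0))
    if (nrow(motions)) {
      for (i in seq_len(nrow(motions))) {
        m <- motions$motion[i]
        fcr_amp  <- if (m %in% fcr_dominant_motions) burst_rms else burst_rms / dominance_ratio
        ecrl_amp <- if (m %in% fcr_dominant_motions) burst_rms / dominance_ratio else burst_rms
        tr <- trapezoid(t_ms, motions$onset_ms[i],
                        motions$onset_ms[i] + motions$duration_ms[i], ramp_ms)
        env_f <- pmax(env_f, fcr_amp * tr)
        env_e <- pmax(env_e, ecrl_amp * tr)
        amps <- rbind(amps, data.frame(motion = m, fcr_amp = fcr_amp,
                                       ecrl_amp = ecrl_amp))
      }
    }
    fcr  <- band_noise(n, fs) * env_f
    ecrl <- band_noise(n, fs) * env_e
    truth <- motions
    if (nrow(motions)) {
      truth$offset_ms <- truth$onset_ms + truth$duration_ms
      truth$fcr_amp <- amps$fcr_amp
      truth$ecrl_amp <- amps$ecrl_amp
      truth$dominant <- ifelse(truth$motion %in% fcr_dominant_motions,
                               "FCR", "ECRL")
    }
    list(fcr = sampled_signal(fcr, fs = fs, channel = "FCR"),
         ecrl = sampled_signal(ecrl, fs = fs, channel = "ECRL"),
         truth = truth)
  })
}

validate_motions <- function(motions) {
  if (is.null(motions) || (is.data.frame(motions) && nrow(motions) == 0L)) {
    return(data.frame(motion = character(0), onset_ms = numeric(0),
                      duration_ms = numeric(0)))
  }
  if (!is.data.frame(motions) ||
      !all(c("motion", "onset_ms", "duration_ms") %in% names(motions))) {
    stop_invalid_parameter(
      "motions must be a data.frame with columns motion, onset_ms, duration_ms")
  }
  if (!all(motions$motion %in% motion_labels)) {
    stop_invalid_parameter(sprintf("motion labels must be one of: %s",
                                   paste(motion_labels, collapse = ", ")))
  }
  if (any(motions$duration_ms <= 0) || any(motions$onset_ms < 0)) {
    stop_invalid_parameter("onsets must be >= 0 and durations > 0")
  }
  o <- order(motions$onset_ms)
  motions <- motions[o, , drop = FALSE]
  ends <- motions$onset_ms + motions$duration_ms
  if (nrow(motions) > 1L &&
      any(motions$onset_ms[-1L] < ends[-nrow(motions)])) {
    stop_invalid_parameter("motion windows must not overlap")
  }
  rownames(motions) <- NULL
  motions
}

# Unit-RMS white noise band-passed to the 20-450 Hz surface-EMG band.
band_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  hi <- min(450, 0.45 * fs)
  bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sqrt(mean(y^2))
}

# Trapezoidal window: 0 outside [on, off], 1 in the plateau, linear ramps.
trapezoid <- function(t_ms, on, off, ramp) {
  up <- (t_ms - on) / ramp
  down <- (off - t_ms) / ramp
  pmax(0, pmin(1, up, down))
}

#' Generate a full synthetic training session
#'
#' Emulates a rehabilitation training session: a continuous ECG whose R-R
#' statistics follow the requested status, and two-channel EMG containing
#' repeated motion bouts whose burst amplitude decays multiplicatively
#' with elapsed time — the progressive drop in muscle-activity intensity
#' seen over long training. With decay `d` per hour, the burst amplitude
#' at minute `t` is the initial amplitude times `(1 - d)^(t/60)`.
#'
#' @param status `"excited"` or `"fatigue"` (drives the R-R series).
#' @param duration_min session length in minutes (>= 1).
#' @param decay fractional amplitude loss per hour, in \[0, 1).
#' @param seed RNG seed.
#' @param fs_ecg,fs_emg sampling rates (Hz).
#' @param noise ECG [noise_spec].
#' @param burst_rms initial dominant-channel burst RMS (V).
#' @param bouts_per_min motion bursts per minute.
#' @param burst_duration_ms single burst length.
#' @return List with `ecg`, `fcr`, `ecrl` ([sampled_signal]s) and `truth`
#'   (R peaks, R-R intervals, status, motion windows, and per-bout mean
#'   envelope amplitudes per channel, one bout per minute).
#' @export
gen_session <- function(status = c("excited", "fatigue"), duration_min = 5,
                        decay = 0.2, seed = NULL, fs_ecg = 500, fs_emg = 1000,
                        noise = noise_spec(), burst_rms = 2.0,
                        bouts_per_min = 4, burst_duration_ms = 3000) {
  status <- match.arg(status)
  if (!is_scalar_num(duration_min) || duration_min < 1) {
    stop_invalid_parameter("duration_min must be >= 1")
  }
  if (!is_scalar_num(decay) || decay < 0 || decay >= 1) {
    stop_invalid_parameter("decay must be in [0, 1)")
  }
  mean_rr <- if (status == "excited") 800 else 900
  n_rr <- ceiling(duration_min * 60000 / mean_rr) + 5L

  seeds <- derive_seeds(seed, 3L)
  rr <- gen_rr_series(status, n = n_rr, mean_rr = mean_rr, seed = seeds[[1]])
  ecg <- gen_ecg(rr, fs = fs_ecg, noise = noise, seed = seeds[[2]])

  # One "bout" per minute; bursts alternate through the four motions.
  gap_ms <- 60000 / bouts_per_min - burst_duration_ms
  if (gap_ms < 1000) stop_invalid_parameter("bursts too dense for the minute grid")
  onsets <- numeric(0); labels <- character(0); amps <- numeric(0)
  k <- 0L
  for (minute in seq_len(ceiling(duration_min)) - 1L) {
    a <- burst_rms * (1 - decay)^(minute / 60)
    for (b in seq_len(bouts_per_min)) {
      on <- minute * 60000 + (b - 1) * (burst_duration_ms + gap_ms) + gap_ms / 2
      if (on + burst_duration_ms > duration_min * 60000) break
      k <- k + 1L
      onsets <- c(onsets, on)
      labels <- c(labels, motion_labels[(k - 1L) %% 4L + 1L])
      amps <- c(amps, a)
    }
  }
  motions <- data.frame(motion = labels, onset_ms = onsets,
                        duration_ms = burst_duration_ms)
  emg <- gen_emg_scaled(motions, amps, fs = fs_emg, seed = seeds[[3]],
                        duration_ms = duration_min * 60000)

  bout_minute <- factor(floor(onsets / 60000))
  tr <- emg$truth
  bout_means <- data.frame(
    minute = as.numeric(levels(bout_minute)),
    fcr_mean_amp = as.numeric(tapply(tr$fcr_amp, bout_minute, mean)),
    ecrl_mean_amp = as.numeric(tapply(tr$ecrl_amp, bout_minute, mean)))
  rownames(bout_means) <- NULL

  list(ecg = ecg$signal, fcr = emg$fcr, ecrl = emg$ecrl,
       truth = list(status = status,
                    r_peak_times = ecg$truth$r_peak_times,
                    rr_intervals = ecg$truth$rr_intervals,
                    motion_windows = tr,
                    bout_means = bout_means))
}

# gen_emg with a per-window amplitude scale (for session decay), dominance
# ratio 2 and baseline 0.1 V as in gen_emg's defaults.
gen_emg_scaled <- function(motions, scale, fs, seed, duration_ms,
                           dominance_ratio = 2.0, baseline_rms = 0.1) {
  tr <- validate_motions(motions)
  tr$offset_ms <- tr$onset_ms + tr$duration_ms
  tr$fcr_amp <- ifelse(tr$motion %in% fcr_dominant_motions,
                       1.0, 1.0 / dominance_ratio) * scale
  tr$ecrl_amp <- ifelse(tr$motion %in% fcr_dominant_motions,
                        1.0 / dominance_ratio, 1.0) * scale
  tr$dominant <- ifelse(tr$motion %in% fcr_dominant_motions, "FCR", "ECRL")

  n <- ceiling(duration_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  env_f <- rep(baseline_rms, n)
  env_e <- rep(baseline_rms, n)
  for (i in seq_len(nrow(tr))) {
    w <- trapezoid(t_ms, tr$onset_ms[i], tr$offset_ms[i], 100)
    env_f <- pmax(env_f, tr$fcr_amp[i] * w)
    env_e <- pmax(env_e, tr$ecrl_amp[i] * w)
  }
  seeds <- derive_seeds(seed, 2L)
  fcr <- with_rng_seed(seeds[[1]], band_noise(n, fs)) * env_f
  ecrl <- with_rng_seed(seeds[[2]], band_noise(n, fs)) * env_e
  list(fcr = sampled_signal(fcr, fs = fs, channel = "FCR"),
       ecrl = sampled_signal(ecrl, fs = fs, channel = "ECRL"),
       truth = tr)
}

# Derive k child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list((as.numeric(seed) * 1009 + seq_len(k) * 7919) %% 2147483647)
}
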