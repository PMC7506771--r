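#' Full-wave rectification
#'
#' Takes the absolute value of every sample, mirroring the full-wave
#' precision rectifier of the analog front end.
#'
#' @param x a [sampled_signal].
#' @return The rectified [sampled_signal].
#' @export
rectify <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  with_samples(x, abs(x$samples))
}

#' Segment RMS of an EMG trace
#'
#' Splits the trace into consecutive non-overlapping segments of `N`
#' samples (a trailing partial segment is dropped) and computes the root
#' mean square sqrt(sum(v_i^2)/N) of each — the muscle-activity intensity
#' feature. Default N = 200 (200 ms at 1 kHz sampling).
#'
#' @param x a [sampled_signal].
#' @param N samples per segment (default 200).
#' @return Object of class `emg_features`: data.frame with `segment`,
#'   `start_ms`, `rms` (V); attributes `N`, `fs`, `channel`.
#' @examples
#' s <- sampled_signal(rep(2, 400), fs = 1000, channel = "FCR")
#' rms_segments(s)$rms  # 2 2
#' @export
rms_segments <- function(x, N = 200) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is_count(N, 1L)) stop_invalid_parameter("N must be a positive integer")
  v <- x$samples
  n_seg <- length(v) %/% N
  if (n_seg < 1L) {
    stop_insufficient_data(sprintf(
      "signal has %d samples; need at least N = %d", length(v), N))
  }
  m <- matrix(v[seq_len(n_seg * N)], nrow = N)
  rms <- sqrt(colMeans(m^2))
  out <- data.frame(segment = seq_len(n_seg),
                    start_ms = x$t0 + (seq_len(n_seg) - 1L) * N * 1000 / x$fs,
                    rms = rms)
  attr(out, "N") <- as.integer(N)
  attr(out, "fs") <- x$fs
  attr(out, "channel") <- x$channel
  class(out) <- c("emg_features", "data.frame")
  out
}

#' Calibrate the benchmark maximal RMS of a channel
#'
#' Before training, the hand is moved to its extreme position to elicit
#' maximal activity; the maximum segment RMS of each trial is taken, the
#' procedure is repeated (three trials by default) and the benchmark
#' RMS_M is their arithmetic mean.
#'
#' @param trials list of [sampled_signal]s (same channel), one per maximal
#'   trial; each long enough for at least one segment.
#' @param N samples per segment (default 200).
#' @return Object of class `calibration_record`: list with `channel`,
#'   `trial_rms` (per-trial maxima, V) and `rms_m` (their mean, V).
#' @export
calibrate_rms_max <- function(trials, N = 200) {
  if (!is.list(trials) || length(trials) < 1L ||
      !all(vapply(trials, inherits, logical(1), "sampled_signal"))) {
    stop_invalid_input("trials must be a non-empty list of sampled_signal")
  }
  ch <- unique(vapply(trials, function(s) s$channel, character(1)))
  if (length(ch) != 1L) stop_invalid_input("all trials must share one channel")
  trial_rms <- vapply(trials, function(s) max(rms_segments(s, N)$rms),
                      numeric(1))
  structure(list(channel = ch, trial_rms = trial_rms,
                 rms_m = mean(trial_rms)),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration_record> channel=%s  RMS_M=%.4g V  (trials: %s)\n",
              x$channel, x$rms_m,
              paste(sprintf("%.4g", x$trial_rms), collapse = ", ")))
  invisible(x)
}

#' Build a calibration record from known trial maxima
#'
#' @param trial_rms per-trial maximum RMS values (V), all > 0.
#' @param channel channel label.
#' @return A `calibration_record`.
#' @export
calibration_record <- function(trial_rms, channel = "FCR") {
  if (any(!is.finite(trial_rms)) || any(trial_rms <= 0)) {
    stop_invalid_parameter("trial_rms must be positive and finite")
  }
  structure(list(channel = channel, trial_rms = as.numeric(trial_rms),
                 rms_m = mean(trial_rms)),
            class = "calibration_record")
}

#' Normalize segment RMS against the calibration benchmark
#'
#' Divides every segment RMS by the channel's benchmark RMS_M, yielding the
#' dimensionless normalized intensity RMS_N = RMS / RMS_M. Values above 1
#' indicate activity exceeding the calibration maximum; values above 0.95
#' are annotated as possibly saturated (the RMS feature stops tracking
#' intensity for very strong contractions).
#'
#' @param series an `emg_features` from [rms_segments()].
#' @param cal a `calibration_record` for the same channel.
#' @return The series with columns `rms_normalized` and `saturated` added;
#'   attribute `rms_m` records the benchmark used.
#' @export
normalize_rms <- function(series, cal) {
  stopifnot(inherits(series, "emg_features"),
            inherits(cal, "calibration_record"))
  if (!is_scalar_num(cal$rms_m) || cal$rms_m <= 0) {
    abort_rehabsig("calibration RMS_M must be > 0", "invalid_calibration")
  }
  ch <- attr(series, "channel")
  if (!is.null(ch) && !is.null(cal$channel) && ch != cal$channel) {
    abort_rehabsig(sprintf("series channel %s but calibration is for %s",
                           ch, cal$channel), "invalid_calibration")
  }
  series$rms_normalized <- series$rms / cal$rms_m
  series$saturated <- series$rms_normalized > 0.95
  attr(series, "rms_m") <- cal$rms_m
  series
}

#' Segment muscle activity from a normalized RMS series
#'
#' Finds maximal runs of segments whose normalized RMS meets the activity
#' threshold. Runs separated by fewer than 2 sub-threshold segments are
#' merged (a single momentary dip does not split a contraction); runs
#' shorter than `min_duration` segments are discarded.
#'
#' @param series a normalized `emg_features` (see [normalize_rms()]).
#' @param threshold activity threshold on RMS_N (default 0.2).
#' @param min_duration minimum run length in segments (default 3).
#' @return data.frame with one row per activity event: `onset_ms`,
#'   `offset_ms`, `n_segments`, `peak_rms_n`, `mean_rms_n`.
#' @export
segment_activity <- function(series, threshold = 0.2, min_duration = 3) {
  stopifnot(inherits(series, "emg_features"))
  if (is.null(series$rms_normalized)) {
    stop_invalid_input("series must be normalized first (see normalize_rms)")
  }
  if (!is_scalar_num(threshold) || threshold <= 0 ||
      !is_count(min_duration, 1L)) {
    stop_invalid_parameter("threshold > 0 and min_duration >= 1 required")
  }
  active <- series$rms_normalized >= threshold
  if (!any(active)) return(empty_events())

  # merge runs separated by a single sub-threshold segment
  r <- rle(active)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  gap <- which(!r$values & r$lengths < 2L)
  gap <- gap[gap > 1L & gap < length(r$values)]
  for (g in gap) active[idx_start[g]:idx_end[g]] <- TRUE

  r <- rle(active)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_duration)
  if (!length(runs)) return(empty_events())

  seg_ms <- attr(series, "N") * 1000 / attr(series, "fs")
  do.call(rbind, lapply(runs, function(g) {
    i <- idx_start[g]:idx_end[g]
    data.frame(onset_ms = series$start_ms[idx_start[g]],
               offset_ms = series$start_ms[idx_end[g]] + seg_ms,
               n_segments = length(i),
               peak_rms_n = max(series$rms_normalized[i]),
               mean_rms_n = mean(series$rms_normalized[i]))
  }))
}

empty_events <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             n_segments = integer(0), peak_rms_n = numeric(0),
             mean_rms_n = numeric(0))
}

#' Motion-group discrimination from two-channel intensities
#'
#' With electrodes on the FCR and ECRL muscles, the relative intensity of
#' the two channels separates the hand motions into two groups: forearm
#' pronation and finger flexion activate the FCR more strongly
#' (FCR-dominant group); hand closing and wrist extension activate the
#' ECRL more strongly (ECRL-dominant group). An exact tie is reported as
#' `"indeterminate"`.
#'
#' @param fcr_event_rms normalized event RMS of the FCR channel.
#' @param ecrl_event_rms normalized event RMS of the ECRL channel.
#' @param threshold activity threshold; at least one channel must reach it.
#' @return `"fcr_dominant"` (forearm pronation / finger flexion),
#'   `"ecrl_dominant"` (hand closing / wrist extension), or
#'   `"indeterminate"`.
#' @examples
#' classify_motion(1.5, 0.8)  # "fcr_dominant"
#' @export
classify_motion <- function(fcr_event_rms, ecrl_event_rms, threshold = 0.2) {
  if (!is_scalar_num(fcr_event_rms) || !is_scalar_num(ecrl_event_rms) ||
      fcr_event_rms < 0 || ecrl_event_rms < 0) {
    stop_invalid_parameter("event RMS values must be finite and >= 0")
  }
  if (fcr_event_rms < threshold && ecrl_event_rms < threshold) {
    abort_rehabsig("both channels below the activity threshold", "no_activity")
  }
  if (fcr_event_rms > ecrl_event_rms) "fcr_dominant"
  else if (ecrl_event_rms > fcr_event_rms) "ecrl_dominant"
  else "indeterminate"
}

#' Detect motion events from a two-channel EMG recording
#'
#' Runs the full EMG feature path on both channels: segment RMS,
#' normalization, joint activity segmentation (a segment is active when
#' either channel crosses the threshold), and per-event dominance
#' classification.
#'
#' @param fcr,ecrl [sampled_signal]s of the two channels (same grid).
#' @param cal_fcr,cal_ecrl `calibration_record`s per channel.
#' @param N samples per segment.
#' @param threshold activity threshold on RMS_N.
#' @param min_duration minimum event length in segments.
#' @return data.frame with one row per event: onset/offset (ms),
#'   `fcr_rms_n`, `ecrl_rms_n` (mean normalized RMS inside the event),
#'   `dominant_channel`, `motion_group`.
#' @export
detect_motion_events <- function(fcr, ecrl, cal_fcr, cal_ecrl, N = 200,
                                 threshold = 0.2, min_duration = 3) {
  f <- normalize_rms(rms_segments(fcr, N), cal_fcr)
  e <- normalize_rms(rms_segments(ecrl, N), cal_ecrl)
  n <- min(nrow(f), nrow(e))
  f <- f[seq_len(n), ]
  e <- e[seq_len(n), ]

  joint <- f
  joint$rms_normalized <- pmax(f$rms_normalized, e$rms_normalized)
  attr(joint, "N") <- attr(f, "N"); attr(joint, "fs") <- attr(f, "fs")
  class(joint) <- class(f)
  ev <- segment_activity(joint, threshold, min_duration)
  if (!nrow(ev)) {
    return(cbind(ev, data.frame(fcr_rms_n = numeric(0),
                                ecrl_rms_n = numeric(0),
                                dominant_channel = character(0),
                                motion_group = character(0))))
  }
  seg_ms <- attr(f, "N") * 1000 / attr(f, "fs")
  ev$fcr_rms_n <- NA_real_; ev$ecrl_rms_n <- NA_real_
  ev$dominant_channel <- NA_character_; ev$motion_group <- NA_character_
  for (i in seq_len(nrow(ev))) {
    in_ev <- f$start_ms >= ev$onset_ms[i] & f$start_ms < ev$offset_ms[i]
    ev$fcr_rms_n[i] <- mean(f$rms_normalized[in_ev])
    ev$ecrl_rms_n[i] <- mean(e$rms_normalized[in_ev])
    grp <- classify_motion(ev$fcr_rms_n[i], ev$ecrl_rms_n[i], threshold)
    ev$motion_group[i] <- grp
    ev$dominant_channel[i] <- switch(grp, fcr_dominant = "FCR",
                                     ecrl_dominant = "ECRL", NA_character_)
  }
  ev
}
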