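# Pipeline configuration and the end-to-end run (the software-platform
# stand-in: monitoring, recording and summary outputs, no GUI).

pipeline_defaults <- function() {
  list(
    seed = 1L,
    status = "excited",            # session status when generating input
    duration_min = 3,
    decay = 0.2,                   # burst-amplitude loss per hour
    noise_preset = "clean",
    fs_ecg = 500, fs_emg = 1000,
    cutoff_hz = 40, baseline_window_ms = 600, artifact_filter = TRUE,
    min_rr_ms = 300, hrv_k = 10L, fatigue_epsilon_ms = 5,
    segment_n = 200L, activity_threshold = 0.2, min_duration_segments = 3L,
    svm_window = 10L, svm_stride = 5L, svm_smoothing = 3L,
    ecg_csv = NULL, emg_csv = NULL,   # optional recorded inputs
    out_dir = NULL
  )
}

#' Build and validate a pipeline configuration
#'
#' Collects every tunable of the processing chain in one validated list.
#' Unknown keys are rejected; numeric fields are checked against the
#' bounds of the stage that consumes them.
#'
#' @param ... named overrides of the defaults (see Details in the package
#'   vignette for the meaning and units of each field).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over))))) {
    stop_invalid_parameter("all configuration entries must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_invalid_parameter(sprintf("unknown configuration key(s): %s",
                                   paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (!cfg$status %in% c("excited", "fatigue")) {
    stop_invalid_parameter("status must be 'excited' or 'fatigue'")
  }
  if (!is_scalar_num(cfg$duration_min) || cfg$duration_min < 1) {
    stop_invalid_parameter("duration_min must be >= 1")
  }
  if (!cfg$noise_preset %in% c("clean", "ambulatory")) {
    stop_invalid_parameter("noise_preset must be 'clean' or 'ambulatory'")
  }
  if (cfg$cutoff_hz >= cfg$fs_ecg / 2) {
    stop_invalid_parameter("cutoff_hz must be below the ECG Nyquist rate")
  }
  if (!is_count(cfg$hrv_k, 2L) || !is_count(cfg$segment_n, 1L)) {
    stop_invalid_parameter("hrv_k >= 2 and segment_n >= 1 required")
  }
  if (!is_scalar_num(cfg$fatigue_epsilon_ms) || cfg$fatigue_epsilon_ms <= 0) {
    stop_invalid_parameter("fatigue_epsilon_ms must be > 0")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format_error(sprintf("file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, doc)
}

#' @param cfg a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  x <- x[order(names(x))]   # canonical key order for round-trip stability
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# One JSON record per line.
write_jsonl <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.data.frame(df)) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  } else {
    for (rec in df) {
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' Run the full monitoring pipeline
#'
#' Generates (or loads) a session, runs ECG conditioning, R-peak/HRV
#' extraction and fatigue-rule status classification, runs the EMG feature
#' path (segment RMS, normalization against synthetic maximal-trial
#' calibration, activity segmentation, motion-group discrimination), and
#' returns a summary. When `cfg$out_dir` is set, all artifacts are written
#' there: conditioned signals and traces as CSV, peaks/HRV/features/events
#' as JSONL, and `summary.json`.
#'
#' @param cfg a [pipeline_config].
#' @return List of class `pipeline_result` with elements `ecg` (peaks, rr,
#'   hrv), `status` (per-window labels, alerts), `emg` (features, events,
#'   calibration), `bout_means`, and `summary` (the JSON-ready list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- derive_seeds(cfg$seed, 4L)

  # ---- inputs: recorded CSVs or the synthetic session generator
  if (!is.null(cfg$ecg_csv) || !is.null(cfg$emg_csv)) {
    if (is.null(cfg$ecg_csv) || is.null(cfg$emg_csv)) {
      stop_invalid_parameter("provide both ecg_csv and emg_csv, or neither")
    }
    ecg_sig <- read_signal_csv(cfg$ecg_csv)
    if (is.list(ecg_sig) && !inherits(ecg_sig, "sampled_signal")) {
      ecg_sig <- ecg_sig[[1]]
    }
    emg <- read_signal_csv(cfg$emg_csv)
    if (inherits(emg, "sampled_signal") || length(emg) < 2L) {
      stop_format_error("emg_csv must contain two value columns (FCR, ECRL)")
    }
    fcr <- emg[[1]]; ecrl <- emg[[2]]
    truth <- NULL
  } else {
    ses <- gen_session(cfg$status, duration_min = cfg$duration_min,
                       decay = cfg$decay, seed = seeds[[1]],
                       fs_ecg = cfg$fs_ecg, fs_emg = cfg$fs_emg,
                       noise = noise_preset(cfg$noise_preset))
    ecg_sig <- ses$ecg; fcr <- ses$fcr; ecrl <- ses$ecrl
    truth <- ses$truth
  }

  # ---- ECG chain
  ecg_res <- process_ecg(ecg_sig, cutoff = cfg$cutoff_hz,
                         baseline_window = cfg$baseline_window_ms,
                         artifact_filter = cfg$artifact_filter,
                         min_rr = cfg$min_rr_ms, hrv_k = cfg$hrv_k)
  if (is.null(ecg_res$hrv)) {
    stop_insufficient_data("too few beats detected for HRV analysis")
  }
  rule <- rule_fatigue(ecg_res$hrv, k = cfg$hrv_k,
                       epsilon = cfg$fatigue_epsilon_ms)
  win_labels <- ifelse(ecg_res$hrv$variation < cfg$fatigue_epsilon_ms,
                       "fatigue", "excited")
  prev <- c("excited", win_labels[-length(win_labels)])
  alerts <- which(win_labels == "fatigue" & prev == "excited")

  heart_rate <- heart_rate_bpm(ecg_res$rr)

  # ---- EMG chain: calibration from three synthetic maximal trials
  cal <- synth_calibration(cfg, seeds[[2]])
  events <- detect_motion_events(fcr, ecrl, cal$fcr, cal$ecrl,
                                 N = cfg$segment_n,
                                 threshold = cfg$activity_threshold,
                                 min_duration = cfg$min_duration_segments)
  feat_f <- normalize_rms(rms_segments(fcr, cfg$segment_n), cal$fcr)
  feat_e <- normalize_rms(rms_segments(ecrl, cfg$segment_n), cal$ecrl)
  bout_means <- per_minute_means(feat_f, feat_e, events)

  summary <- list(
    seed = cfg$seed,
    heart_rate_bpm = heart_rate,
    n_beats = length(ecg_res$peaks$peak_times),
    n_hrv_windows = nrow(ecg_res$hrv),
    fatigue_rule_fired = rule$flag,
    first_fatigue_window = if (rule$flag) rule$first_trigger_index else NULL,
    n_alerts = length(alerts),
    status_timeline = as.list(table(win_labels)),
    n_motion_events = nrow(events),
    motion_groups = as.list(table(events$motion_group)),
    calibration_rms_m = list(FCR = cal$fcr$rms_m, ECRL = cal$ecrl$rms_m),
    bout_mean_rms_V = bout_means
  )

  res <- structure(list(ecg = ecg_res,
                        status = list(labels = win_labels, alerts = alerts,
                                      rule = rule),
                        emg = list(fcr = feat_f, ecrl = feat_e,
                                   events = events, calibration = cal),
                        bout_means = bout_means, truth = truth,
                        summary = summary),
                   class = "pipeline_result")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  heart rate: %.1f bpm over %d beats; %d HRV windows\n",
              s$heart_rate_bpm, s$n_beats, s$n_hrv_windows))
  cat(sprintf("  fatigue rule fired: %s (%d alert%s)\n",
              s$fatigue_rule_fired, s$n_alerts,
              if (s$n_alerts == 1) "" else "s"))
  cat(sprintf("  motion events: %d (%s)\n", s$n_motion_events,
              paste(names(s$motion_groups), unlist(s$motion_groups),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Mean heart rate in bpm from 30-s sliding windows over the beat series.
heart_rate_bpm <- function(rr, window_ms = 30000) {
  t <- rr$anchor_times
  if (length(t) < 2L) return(60000 / mean(rr$intervals))
  starts <- seq(t[1], max(t[1], t[length(t)] - window_ms), by = window_ms / 2)
  rates <- vapply(starts, function(s) {
    in_w <- t >= s & t < s + window_ms
    if (sum(in_w) < 2L) return(NA_real_)
    60000 / mean(rr$intervals[in_w])
  }, numeric(1))
  rates <- rates[is.finite(rates)]
  if (!length(rates)) 60000 / mean(rr$intervals) else mean(rates)
}

# Three synthetic maximal-effort trials per channel at the session's burst
# scale; mirrors the pre-training manual calibration protocol.
synth_calibration <- function(cfg, seed, burst_rms = 2.0) {
  seeds <- derive_seeds(seed, 6L)
  mk <- function(channel, s) {
    m <- data.frame(motion = if (channel == "FCR") "finger_flexion"
                             else "wrist_extension",
                    onset_ms = 200, duration_ms = 1500)
    g <- gen_emg(m, fs = cfg$fs_emg, seed = s, duration_ms = 2000,
                 burst_rms = burst_rms)
    if (channel == "FCR") g$fcr else g$ecrl
  }
  cal_f <- calibrate_rms_max(lapply(1:3, function(i) mk("FCR", seeds[[i]])),
                             N = cfg$segment_n)
  cal_e <- calibrate_rms_max(lapply(4:6, function(i) mk("ECRL", seeds[[i]])),
                             N = cfg$segment_n)
  list(fcr = cal_f, ecrl = cal_e)
}

# Per-minute mean segment RMS per channel (the bout summary). Averaged over
# segments inside detected activity events, so the value reads as bout
# muscle intensity; falls back to all segments when no events were found.
per_minute_means <- function(feat_f, feat_e, events = NULL) {
  keep <- rep(TRUE, nrow(feat_f))
  if (!is.null(events) && nrow(events)) {
    keep <- vapply(feat_f$start_ms, function(s) {
      any(s >= events$onset_ms & s < events$offset_ms)
    }, logical(1))
  }
  minute <- factor(floor(feat_f$start_ms[keep] / 60000))
  data.frame(minute = as.numeric(levels(minute)),
             fcr_mean_rms = as.numeric(tapply(feat_f$rms[keep], minute, mean)),
             ecrl_mean_rms = as.numeric(
               tapply(feat_e$rms[seq_len(nrow(feat_f))][keep], minute, mean)))
}

write_pipeline_outputs <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  pk <- res$ecg$peaks
  write_jsonl(data.frame(time_ms = pk$peak_times,
                         amplitude_V = pk$peak_amplitudes), p("rpeaks.jsonl"))
  write_jsonl(as.data.frame(res$ecg$hrv), p("hrv.jsonl"))
  write_jsonl(data.frame(window = seq_along(res$status$labels),
                         label = res$status$labels), p("status.jsonl"))
  write_jsonl(as.data.frame(res$emg$fcr), p("emg_fcr_features.jsonl"))
  write_jsonl(as.data.frame(res$emg$ecrl), p("emg_ecrl_features.jsonl"))
  write_jsonl(res$emg$events, p("motion_events.jsonl"))
  jsonlite::write_json(res$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cfg$out_dir)
}
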