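#' Zero-phase low-pass filter
#'
#' Removes high-frequency interference from an ECG trace with a 4th-order
#' Butterworth low-pass applied forward and backward (zero phase), so R-peak
#' timing is preserved. The default 40 Hz cutoff keeps the QRS band while
#' rejecting powerline pickup and EMG crosstalk.
#'
#' @param x a [sampled_signal].
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @return The filtered [sampled_signal].
#' @export
lowpass_filter <- function(x, cutoff = 40) {
  stopifnot(inherits(x, "sampled_signal"))
  if (!is_scalar_num(cutoff) || cutoff <= 0 || cutoff >= x$fs / 2) {
    stop_invalid_parameter("cutoff must be in (0, fs/2)")
  }
  bf <- signal::butter(4, cutoff / (x$fs / 2), type = "low")
  with_samples(x, signal::filtfilt(bf, x$samples))
}

#' Baseline-wander removal by sliding-window median
#'
#' Estimates the slowly varying baseline as the sliding median of the trace
#' and subtracts it. The window (default 600 ms) is longer than any single
#' QRS complex, so the median tracks drift without degrading the beat
#' morphology. Edges are handled by reflection padding.
#'
#' @param x a [sampled_signal].
#' @param window median window length in ms; must span at least 3 samples.
#' @return The baseline-corrected [sampled_signal].
#' @export
remove_baseline_median <- function(x, window = 600) {
  stopifnot(inherits(x, "sampled_signal"))
  k <- round(window * x$fs / 1000)
  if (k %% 2 == 0) k <- k + 1L
  if (!is_scalar_num(window) || k < 3L) {
    stop_invalid_parameter("window must span at least 3 samples")
  }
  if (k > length(x$samples)) {
    stop_invalid_parameter("window longer than the signal")
  }
  with_samples(x, x$samples - sliding_median(x$samples, k))
}

# Sliding median with reflection padding; k odd.
sliding_median <- function(v, k) {
  h <- (k - 1L) %/% 2L
  n <- length(v)
  pad <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
  m <- stats::runmed(pad, k, endrule = "keep")
  m[(h + 1L):(h + n)]
}

#' Suppress transient artifacts by an adaptive robust threshold
#'
#' Motion of the electrodes produces short, large-amplitude transients that
#' corrupt QRS detection. The filter computes the residual of each sample
#' against a short (7-sample) running median — smooth physiological waves
#' leave a tiny residual, isolated spikes a large one — and replaces samples
#' whose |residual| exceeds `k_mad` times the running median absolute
#' deviation (MAD) of the residual, plus a small absolute floor, by linear
#' interpolation of the neighboring clean samples. On a clean trace no
#' sample crosses the threshold and the output equals the input.
#'
#' @param x a [sampled_signal].
#' @param k_mad threshold multiplier on the running MAD (default 8).
#' @param med_window running-median width in ms (default 14; short enough
#'   that smooth QRS curvature leaves a negligible residual).
#' @param mad_window window for the running MAD, in ms (default 1000).
#' @param floor_abs absolute threshold floor in V (default 0.1); guards the
#'   near-zero-MAD regime of very clean traces.
#' @return The artifact-suppressed [sampled_signal].
#' @export
suppress_artifacts <- function(x, k_mad = 8, med_window = 14,
                               mad_window = 1000, floor_abs = 0.1) {
  stopifnot(inherits(x, "sampled_signal"))
  v <- x$samples
  n <- length(v)
  med_k <- round(med_window * x$fs / 1000)
  if (med_k %% 2 == 0) med_k <- med_k + 1L
  med_k <- max(med_k, 3L)
  if (n < med_k + 2L) return(x)

  res <- v - sliding_median(v, med_k)
  kw <- round(mad_window * x$fs / 1000)
  if (kw %% 2 == 0) kw <- kw + 1L
  kw <- min(kw, if (n %% 2 == 0) n - 1L else n)
  mad_run <- 1.4826 * sliding_median(abs(res), kw)
  if (all(mad_run == 0) && floor_abs <= 0) return(x)  # constant signal

  thr <- k_mad * mad_run + floor_abs
  flagged <- abs(res) > thr
  if (!any(flagged)) return(x)

  # grow the mask so the full artifact event (whose center the short
  # median can track) is replaced, not just its edges
  bad <- which(flagged)
  half <- (med_k - 1L) %/% 2L + 1L
  bad <- unique(unlist(lapply(bad, function(i) {
    max(1L, i - half):min(n, i + half)
  })))
  good <- setdiff(seq_len(n), bad)
  if (length(good) < 2L) return(x)
  v[bad] <- stats::approx(good, v[good], xout = bad, rule = 2)$y
  with_samples(x, v)
}

#' Detect R peaks by the differential-threshold method
#'
#' Works on a conditioned trace (low-pass filtered, baseline removed,
#' artifacts suppressed). Candidate peaks are the local maxima found where
#' the first-order difference changes sign from positive to negative.
#' Within each processing chunk (default 10 s, bounding the effect of slow
#' amplitude drift) the amplitude threshold is set to half the largest
#' candidate amplitude, discarding P/T waves and residual clutter. Finally
#' candidates closer together than the minimum R-R interval are resolved by
#' keeping the larger-amplitude one (singularity removal).
#'
#' @param x a conditioned [sampled_signal] of at least 2 s.
#' @param min_rr minimum physiological R-R interval in ms (default 300,
#'   i.e. 200 bpm).
#' @param chunk_s processing-chunk length in seconds for the half-max
#'   threshold (default 10).
#' @return An object of class `rpeak_series`: list with `peak_times` (ms),
#'   `peak_indices`, `peak_amplitudes` (V), `fs`.
#' @export
detect_r_peaks <- function(x, min_rr = 300, chunk_s = 10) {
  stopifnot(inherits(x, "sampled_signal"))
  v <- x$samples
  n <- length(v)
  if (n / x$fs < 2) {
    stop_invalid_input("signal shorter than 2 s; cannot detect R peaks")
  }
  if (!is_scalar_num(min_rr) || min_rr <= 0) {
    stop_invalid_parameter("min_rr must be > 0")
  }

  # local maxima: first difference changes + -> (- or 0); flat-top
  # plateaus contribute their first sample
  s <- sign(diff(v))
  cand <- which(s[-length(s)] > 0 & s[-1L] <= 0) + 1L
  cand <- cand[v[cand] > 0]
  if (!length(cand)) return(empty_rpeaks(x$fs))

  chunk_n <- max(1L, round(chunk_s * x$fs))
  keep <- logical(length(cand))
  for (c0 in seq(1L, n, by = chunk_n)) {
    in_chunk <- cand >= c0 & cand < c0 + chunk_n
    if (!any(in_chunk)) next
    thr <- 0.5 * max(v[cand[in_chunk]])
    keep[in_chunk] <- v[cand[in_chunk]] >= thr
  }
  cand <- cand[keep]
  if (!length(cand)) return(empty_rpeaks(x$fs))

  # singularity removal: among peaks closer than min_rr keep the larger
  min_gap <- min_rr * x$fs / 1000
  repeat {
    gaps <- diff(cand)
    i <- which(gaps < min_gap)
    if (!length(i)) break
    i <- i[1]
    drop <- if (v[cand[i]] >= v[cand[i + 1L]]) i + 1L else i
    cand <- cand[-drop]
  }

  t_ms <- signal_times(x)
  structure(list(peak_times = t_ms[cand],
                 peak_indices = cand,
                 peak_amplitudes = v[cand],
                 fs = x$fs),
            class = "rpeak_series")
}

empty_rpeaks <- function(fs) {
  structure(list(peak_times = numeric(0), peak_indices = integer(0),
                 peak_amplitudes = numeric(0), fs = fs),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks", length(x$peak_times)))
  if (length(x$peak_times) >= 2L) {
    rr <- diff(x$peak_times)
    cat(sprintf("  mean RR=%.1f ms (%.1f bpm)", mean(rr), 60000 / mean(rr)))
  }
  cat("\n")
  invisible(x)
}

#' R-R intervals from detected peaks
#'
#' The heartbeat intervals: successive differences of the R-peak times.
#' Their sum equals the span from first to last peak exactly.
#'
#' @param peaks an `rpeak_series` with at least 2 peaks.
#' @return Object of class `rr_series`: list with `intervals` (ms) and
#'   `anchor_times` (ms; the time of the later peak of each pair).
#' @export
compute_rr <- function(peaks) {
  stopifnot(inherits(peaks, "rpeak_series"))
  if (length(peaks$peak_times) < 2L) {
    stop_insufficient_data("need at least 2 peaks to form R-R intervals")
  }
  structure(list(intervals = diff(peaks$peak_times),
                 anchor_times = peaks$peak_times[-1L]),
            class = "rr_series")
}

#' Construct an rr_series from raw intervals
#'
#' Convenience for feeding generator output (or externally recorded
#' intervals) to the HRV and fatigue stages directly.
#'
#' @param intervals positive R-R intervals in ms.
#' @param t0 time of the (virtual) first peak, ms.
#' @return An `rr_series`.
#' @export
rr_series <- function(intervals, t0 = 0) {
  if (!is.numeric(intervals) || any(!is.finite(intervals)) ||
      any(intervals <= 0)) {
    stop_invalid_parameter("intervals must be positive and finite")
  }
  structure(list(intervals = as.numeric(intervals),
                 anchor_times = t0 + cumsum(intervals)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals  mean=%.1f ms  sd=%.2f ms\n",
              length(x$intervals), mean(x$intervals),
              stats::sd(x$intervals)))
  invisible(x)
}

#' Windowed heart-rate-variability statistics
#'
#' Slides a window of `k` consecutive R-R intervals (stride 1) and reports
#' per window: `variation` (max - min, the statistic the fatigue rule
#' thresholds), `mean_rr`, `sdnn` (sample SD of the intervals), and `rmssd`
#' (root mean square of successive differences).
#'
#' @param rr an `rr_series`.
#' @param k window size in beats (default 10).
#' @return A data.frame of class `hrv_windows` with one row per window and
#'   columns `start`, `anchor_time`, `variation`, `mean_rr`, `sdnn`,
#'   `rmssd`; attribute `window_size` records `k`.
#' @examples
#' hrv_windows(rr_series(c(101, 80, 113)), k = 3)$variation  # 33
#' @export
hrv_windows <- function(rr, k = 10) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is_count(k, min = 2L)) stop_invalid_parameter("k must be an integer >= 2")
  v <- rr$intervals
  n <- length(v)
  if (n < k) {
    stop_insufficient_data(sprintf("need >= %d intervals, got %d", k, n))
  }
  m <- n - k + 1L
  out <- data.frame(start = seq_len(m),
                    anchor_time = rr$anchor_times[seq_len(m) + k - 1L],
                    variation = numeric(m), mean_rr = numeric(m),
                    sdnn = numeric(m), rmssd = numeric(m))
  for (i in seq_len(m)) {
    w <- v[i:(i + k - 1L)]
    out$variation[i] <- max(w) - min(w)
    out$mean_rr[i] <- mean(w)
    out$sdnn[i] <- stats::sd(w)
    out$rmssd[i] <- sqrt(mean(diff(w)^2))
  }
  attr(out, "window_size") <- as.integer(k)
  class(out) <- c("hrv_windows", "data.frame")
  out
}

#' Mark P, Q, S and T waves around detected R peaks
#'
#' Annotation only; feeds no downstream computation. Q and S are the local
#' minima immediately before/after each R within a 200 ms search window;
#' P and T are the largest local maxima in the 200 ms preceding Q and the
#' 400 ms following S.
#'
#' @param x the conditioned [sampled_signal].
#' @param peaks an `rpeak_series` from [detect_r_peaks()].
#' @return data.frame with one row per beat: times (ms) of P, Q, R, S, T
#'   (NA where a wave is not found).
#' @export
mark_waves <- function(x, peaks) {
  stopifnot(inherits(x, "sampled_signal"), inherits(peaks, "rpeak_series"))
  v <- x$samples
  t_ms <- signal_times(x)
  fs <- x$fs
  win <- function(ms) max(1L, round(ms * fs / 1000))
  one <- function(idx) {
    q_rng <- max(1L, idx - win(200)):max(1L, idx - 1L)
    q <- q_rng[which.min(v[q_rng])]
    s_rng <- min(length(v), idx + 1L):min(length(v), idx + win(200))
    s <- s_rng[which.min(v[s_rng])]
    p_rng <- max(1L, q - win(200)):max(1L, q - 1L)
    p <- p_rng[which.max(v[p_rng])]
    t_rng <- min(length(v), s + 1L):min(length(v), s + win(400))
    tw <- t_rng[which.max(v[t_rng])]
    c(P = t_ms[p], Q = t_ms[q], R = t_ms[idx], S = t_ms[s], T = t_ms[tw])
  }
  if (!length(peaks$peak_indices)) {
    return(data.frame(P = numeric(0), Q = numeric(0), R = numeric(0),
                      S = numeric(0), T = numeric(0)))
  }
  as.data.frame(do.call(rbind, lapply(peaks$peak_indices, one)))
}

#' Full ECG conditioning and feature-extraction pipeline
#'
#' Applies, in order: 40 Hz low-pass, sliding-median baseline removal,
#' adaptive artifact suppression (optional), R-peak detection, R-R
#' extraction and windowed HRV statistics.
#'
#' @param x the raw ECG [sampled_signal].
#' @param cutoff low-pass cutoff (Hz).
#' @param baseline_window median window (ms).
#' @param artifact_filter apply [suppress_artifacts()]? Default TRUE.
#' @param min_rr minimum R-R interval (ms) for the detector.
#' @param hrv_k HRV window size in beats.
#' @return List with `conditioned` signal, `peaks`, `rr`, `hrv`.
#' @export
process_ecg <- function(x, cutoff = 40, baseline_window = 600,
                        artifact_filter = TRUE, min_rr = 300, hrv_k = 10) {
  y <- lowpass_filter(x, cutoff)
  y <- remove_baseline_median(y, baseline_window)
  if (artifact_filter) y <- suppress_artifacts(y)
  peaks <- detect_r_peaks(y, min_rr = min_rr)
  rr <- if (length(peaks$peak_times) >= 2L) compute_rr(peaks) else NULL
  hrv <- if (!is.null(rr) && length(rr$intervals) >= hrv_k) {
    hrv_windows(rr, k = hrv_k)
  } else NULL
  list(conditioned = y, peaks = peaks, rr = rr, hrv = hrv)
}
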