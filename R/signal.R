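#' Uniformly sampled voltage trace
#'
#' The basic container for a single-channel biosignal: a numeric vector of
#' voltage samples taken at a fixed sampling rate, starting at time `t0`.
#' Channels are labelled `"ECG"` for the electrocardiogram or `"FCR"` /
#' `"ECRL"` for the two surface-EMG forearm channels (flexor carpi radialis
#' and extensor carpi radialis longus).
#'
#' @param samples numeric vector of voltages (V); must be finite, length >= 1.
#' @param fs sampling rate in Hz; must be > 0.
#' @param t0 start time in ms (default 0).
#' @param channel channel label, one of `"ECG"`, `"FCR"`, `"ECRL"`.
#' @return An object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * (0:499) / 500), fs = 500)
#' s
#' @export
sampled_signal <- function(samples, fs, t0 = 0, channel = "ECG") {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop_invalid_parameter("samples must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) {
    stop_invalid_parameter("all samples must be finite")
  }
  if (!is_scalar_num(fs) || fs <= 0) {
    stop_invalid_parameter("fs must be a single positive number (Hz)")
  }
  channel <- match.arg(channel, c("ECG", "FCR", "ECRL"))
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), channel = channel),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<sampled_signal> channel=%s  fs=%g Hz  n=%d  duration=%.2f s  t0=%g ms\n",
              x$channel, x$fs, length(x$samples), dur, x$t0))
  cat(sprintf("  range: [%.4g, %.4g] V\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Sample times of a signal
#'
#' @param x a [sampled_signal].
#' @return numeric vector of times in ms, one per sample.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$samples) - 1L) * 1000 / x$fs
}

# Replace the sample vector, keeping metadata.
with_samples <- function(x, samples) {
  x$samples <- samples
  x
}

#' Read a sampled signal from CSV
#'
#' Expects a header with a `time_ms` column plus one or more value columns
#' (voltages in V). Sampling must be uniform: the maximum deviation of any
#' timestep from the median timestep may not exceed 1% of the median. The
#' sampling rate is inferred from the median timestep.
#'
#' @param path path to a CSV file.
#' @param channels optional character vector of value columns to read; by
#'   default every non-time column is returned.
#' @return A single [sampled_signal] if one value column is read, otherwise a
#'   named list of them.
#' @export
read_signal_csv <- function(path, channels = NULL) {
  if (!file.exists(path)) stop_format_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_ms" %in% names(df)) {
    stop_format_error("missing required column 'time_ms'")
  }
  value_cols <- setdiff(names(df), "time_ms")
  if (!is.null(channels)) {
    missing <- setdiff(channels, value_cols)
    if (length(missing)) {
      stop_format_error(sprintf("missing column(s): %s",
                                paste(missing, collapse = ", ")))
    }
    value_cols <- channels
  }
  if (length(value_cols) < 1L) stop_format_error("no value column in header")
  if (nrow(df) < 2L) stop_format_error("need at least 2 rows to infer fs")

  tm <- df$time_ms
  if (!is.numeric(tm) || anyNA(tm)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tm))))[1]
    stop_format_error(sprintf("non-numeric time_ms at line %d", bad + 1L))
  }
  dt <- diff(tm)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1]
    stop_format_error(sprintf("non-monotone time_ms at line %d", bad + 2L))
  }
  med_dt <- stats::median(dt)
  if (max(abs(dt - med_dt)) > 0.01 * med_dt) {
    bad <- which.max(abs(dt - med_dt))
    stop_format_error(sprintf("non-uniform sampling at line %d (dt=%g ms, expected %g ms)",
                              bad + 2L, dt[bad], med_dt))
  }
  fs <- 1000 / med_dt

  out <- lapply(value_cols, function(col) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop_format_error(sprintf("non-numeric value in column '%s' at line %d",
                                col, bad + 1L))
    }
    ch <- if (toupper(col) %in% c("ECG", "FCR", "ECRL")) toupper(col) else "ECG"
    sampled_signal(v, fs = fs, t0 = tm[1], channel = ch)
  })
  names(out) <- value_cols
  if (length(out) == 1L) out[[1]] else out
}

#' Write sampled signal(s) to CSV
#'
#' Writes a `time_ms` column plus one value column per signal. All signals
#' must share the same sampling grid.
#'
#' @param x a [sampled_signal] or a named list of them on a common grid.
#' @param path output path.
#' @param col_names optional column names for the value columns; defaults to
#'   the channel labels.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, col_names = NULL) {
  if (inherits(x, "sampled_signal")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "sampled_signal")))
  n <- length(x[[1]]$samples)
  if (!all(vapply(x, function(s) length(s$samples) == n, logical(1)))) {
    stop_invalid_input("all signals must have the same length to share a grid")
  }
  tm <- signal_times(x[[1]])
  vals <- lapply(x, function(s) s$samples)
  if (is.null(col_names)) {
    col_names <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
                 else vapply(x, function(s) s$channel, character(1))
  }
  df <- data.frame(time_ms = tm, vals, check.names = FALSE)
  names(df) <- c("time_ms", col_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
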