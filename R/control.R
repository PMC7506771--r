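#' Controller state for the adaptive glove-pressure strategy
#'
#' The pneumatic glove assists repetitive hand training; the controller
#' holds a predetermined muscle-activity setpoint (e.g. ECRL intensity
#' 1.5 V) by adjusting pump pressure from the gap between setpoint and
#' measured EMG intensity. On detected fatigue the pressure is attenuated
#' and the setpoint ramped down to protect the muscles. Pressure commands
#' are clipped to the pump's 0-75 kPa range.
#'
#' @param pressure_cmd initial pressure command (kPa, in \[0, 75\]).
#' @param setpoint target muscle-activity intensity (V).
#' @param gain proportional gain (kPa per V of error); must be > 0.
#' @param fatigue_scale multiplicative pressure attenuation applied per
#'   fatigue-confirmed step, in (0, 1\].
#' @param setpoint_ramp fractional setpoint reduction per fatigue step.
#' @param p_max pump pressure ceiling (kPa).
#' @return Object of class `control_state`.
#' @export
control_state <- function(pressure_cmd = 0, setpoint = 1.5, gain = 25,
                          fatigue_scale = 0.8, setpoint_ramp = 0.1,
                          p_max = 75) {
  if (!is_scalar_num(gain) || gain <= 0) {
    stop_invalid_parameter("gain must be > 0")
  }
  if (!is_scalar_num(fatigue_scale) || fatigue_scale <= 0 ||
      fatigue_scale > 1) {
    stop_invalid_parameter("fatigue_scale must be in (0, 1]")
  }
  if (!is_scalar_num(pressure_cmd) || pressure_cmd < 0 ||
      pressure_cmd > p_max) {
    stop_invalid_parameter(sprintf("pressure_cmd must be in [0, %g] kPa", p_max))
  }
  structure(list(pressure_cmd = pressure_cmd, setpoint = setpoint,
                 gain = gain, fatigue_scale = fatigue_scale,
                 setpoint_ramp = setpoint_ramp, p_max = p_max),
            class = "control_state")
}

#' One step of the adaptive pressure controller
#'
#' Proportional update: the pressure command moves by `gain` times the gap
#' between setpoint and measured intensity ("strengthened" when activity
#' falls short of the target). If the subject is in the fatigue status the
#' command is additionally scaled by `fatigue_scale` and the setpoint
#' ramped down by `setpoint_ramp` ("weakened" to prevent secondary
#' injury). The result is clipped to \[0, p_max\] kPa.
#'
#' @param state a [control_state].
#' @param measured_rms measured muscle-activity intensity (V, >= 0).
#' @param status `"excited"` or `"fatigue"`.
#' @return The updated `control_state`.
#' @export
control_step <- function(state, measured_rms, status = c("excited", "fatigue")) {
  stopifnot(inherits(state, "control_state"))
  status <- match.arg(status)
  if (!is_scalar_num(measured_rms) || measured_rms < 0) {
    stop_invalid_parameter("measured_rms must be >= 0")
  }
  err <- state$setpoint - measured_rms
  p <- state$pressure_cmd + state$gain * err
  if (status == "fatigue") {
    p <- p * state$fatigue_scale
    state$setpoint <- state$setpoint * (1 - state$setpoint_ramp)
  }
  state$pressure_cmd <- min(max(p, 0), state$p_max)
  state
}

#' Simulated muscle-response plant
#'
#' Stand-in for the human + glove system: a baseline muscle-activity
#' intensity that decays multiplicatively with training time (fatigue),
#' plus a linear assist term proportional to glove pressure, plus Gaussian
#' measurement noise. With decay `d` per hour the baseline after `t`
#' minutes is `baseline * (1 - d)^(t/60)`.
#'
#' @param baseline_intensity initial muscle-activity intensity (V).
#' @param fatigue_decay fractional intensity loss per hour, in \[0, 1).
#' @param assist_gain intensity gained per kPa of glove pressure (V/kPa).
#' @param noise_sd measurement noise SD (V).
#' @return Object of class `plant_state` (elapsed time starts at 0).
#' @export
plant_state <- function(baseline_intensity = 2.0, fatigue_decay = 0.3,
                        assist_gain = 0.02, noise_sd = 0.05) {
  if (!is_scalar_num(assist_gain) || assist_gain <= 0) {
    stop_invalid_parameter("assist_gain must be > 0")
  }
  if (!is_scalar_num(fatigue_decay) || fatigue_decay < 0 || fatigue_decay >= 1) {
    stop_invalid_parameter("fatigue_decay must be in [0, 1) per hour")
  }
  if (baseline_intensity < 0 || noise_sd < 0) {
    stop_invalid_parameter("baseline_intensity and noise_sd must be >= 0")
  }
  structure(list(baseline_intensity = baseline_intensity,
                 fatigue_decay = fatigue_decay, assist_gain = assist_gain,
                 noise_sd = noise_sd, elapsed_min = 0),
            class = "plant_state")
}

#' One step of the simulated plant
#'
#' Advances the plant by `dt_min` minutes under the given pressure command
#' and returns the measured muscle intensity. Draws one noise value from
#' the current RNG stream (seed the surrounding simulation, e.g. via
#' [run_session()]).
#'
#' @param plant a [plant_state].
#' @param pressure_cmd applied pressure (kPa).
#' @param dt_min step length in minutes (> 0).
#' @return List with `plant` (updated state) and `measured_rms` (V).
#' @export
plant_step <- function(plant, pressure_cmd, dt_min) {
  stopifnot(inherits(plant, "plant_state"))
  if (!is_scalar_num(dt_min) || dt_min <= 0) {
    stop_invalid_parameter("dt_min must be > 0")
  }
  plant$baseline_intensity <- plant$baseline_intensity *
    (1 - plant$fatigue_decay)^(dt_min / 60)
  plant$elapsed_min <- plant$elapsed_min + dt_min
  noise <- if (plant$noise_sd > 0) stats::rnorm(1, 0, plant$noise_sd) else 0
  measured <- plant$baseline_intensity +
    plant$assist_gain * pressure_cmd + noise
  list(plant = plant, measured_rms = max(0, measured))
}

#' Run a closed-loop (or open-loop) training-session simulation
#'
#' Loops plant and controller at the EMG segment cadence (default
#' N/fs = 0.2 s). When `adaptive = TRUE` the controller updates the
#' pressure each step; otherwise the pressure is held at its initial
#' constant — the contrast between a glove with and without the adaptive
#' strategy. The fatigue status driving the controller comes from the
#' threshold rule applied to the supplied R-R source: once a 10-beat
#' window with variation under 5 ms has occurred (at or before the current
#' simulation time), the status is fatigue from then on.
#'
#' @param adaptive logical; apply the controller?
#' @param duration_min session length (>= 1 min).
#' @param plant a [plant_state].
#' @param control a [control_state].
#' @param ecg_source `"excited"` or `"fatigue"` (status fixed for the whole
#'   session), or an `rr_series` evaluated by the fatigue rule.
#' @param seed RNG seed for the plant noise.
#' @param dt_min step length in minutes (default 0.2 s).
#' @param rule_k,rule_epsilon fatigue-rule parameters.
#' @return Object of class `session_trace`: data.frame with `time_ms`,
#'   `measured_rms_V`, `pressure_kPa`, `status`, `setpoint_V`.
#' @export
run_session <- function(adaptive, duration_min, plant = plant_state(),
                        control = control_state(), ecg_source = "excited",
                        seed = NULL, dt_min = 0.2 / 60,
                        rule_k = 10, rule_epsilon = 5) {
  if (!is_scalar_num(duration_min) || duration_min < 1) {
    stop_invalid_parameter("duration_min must be >= 1")
  }
  n_steps <- floor(duration_min / dt_min)

  # status timeline: fixed label, or latched rule firing on an R-R series
  fatigue_from_ms <- Inf
  if (inherits(ecg_source, "rr_series")) {
    if (length(ecg_source$intervals) >= rule_k) {
      h <- hrv_windows(ecg_source, k = rule_k)
      r <- rule_fatigue(h, k = rule_k, epsilon = rule_epsilon)
      if (r$flag) fatigue_from_ms <- h$anchor_time[r$first_trigger_index]
    }
  } else {
    src <- match.arg(ecg_source, c("excited", "fatigue"))
    if (src == "fatigue") fatigue_from_ms <- 0
  }

  with_rng_seed(seed, {
    out <- data.frame(time_ms = numeric(n_steps),
                      measured_rms_V = numeric(n_steps),
                      pressure_kPa = numeric(n_steps),
                      status = character(n_steps),
                      setpoint_V = numeric(n_steps))
    for (i in seq_len(n_steps)) {
      st <- plant_step(plant, control$pressure_cmd, dt_min)
      plant <- st$plant
      t_ms <- plant$elapsed_min * 60000
      status <- if (t_ms >= fatigue_from_ms) "fatigue" else "excited"
      if (adaptive) {
        control <- control_step(control, st$measured_rms, status)
      }
      out$time_ms[i] <- t_ms
      out$measured_rms_V[i] <- st$measured_rms
      out$pressure_kPa[i] <- control$pressure_cmd
      out$status[i] <- status
      out$setpoint_V[i] <- control$setpoint
    }
    class(out) <- c("session_trace", "data.frame")
    out
  })
}

#' @export
print.session_trace <- function(x, ...) {
  n <- nrow(x)
  third <- max(1L, floor(n / 3))
  cat(sprintf("<session_trace> %d steps over %.1f min\n", n,
              x$time_ms[n] / 60000))
  cat(sprintf("  mean measured RMS: first third %.3f V, final third %.3f V\n",
              mean(x$measured_rms_V[seq_len(third)]),
              mean(x$measured_rms_V[(n - third + 1L):n])))
  cat(sprintf("  pressure range: [%.1f, %.1f] kPa;  fatigue steps: %d\n",
              min(x$pressure_kPa), max(x$pressure_kPa),
              sum(x$status == "fatigue")))
  invisible(x)
}

#' Write / read a session trace as CSV
#'
#' @param trace a `session_trace`.
#' @param path CSV path.
#' @return `path` invisibly; `read_session_trace` returns the trace.
#' @export
write_session_trace <- function(trace, path) {
  stopifnot(inherits(trace, "session_trace"))
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_trace
#' @export
read_session_trace <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("session_trace", "data.frame")
  df
}
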