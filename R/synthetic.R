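#' Synthetic trace generator
#'
#' Builds a trace with the exact shape of a [run_trial()] recording —
#' a minimum-jerk elbow trajectory plus parameterized Gaussian activity
#' bumps on any membrane-potential channel — for exercising the
#' evaluation stack (template fitting, cost, peak detection, triphasic
#' classification) without running the simulator.
#'
#' @param amplitude,duration,onset minimum-jerk trajectory parameters
#'   (degrees, s, s); `amplitude = 0` gives a flat trace.
#' @param noise_sd sd of white Gaussian angle noise (degrees); the speed
#'   channel stays the analytic template speed.
#' @param bumps named list mapping channel names (e.g. `"flex_emg"`,
#'   `"FlxAlpha"`) to tibbles/data frames with columns `time`, `amp`
#'   (mV above that channel's rest) and `width` (Gaussian sd, s).
#' @param record_dt,total_duration sampling interval and trace length (s).
#' @param theta0 starting angle (degrees).
#' @return A `spinal_trace` tibble (same columns as [run_trial()]).
#' @export
synth_trace <- function(amplitude = 40, duration = 0.8, onset = 5,
                        noise_sd = 0, bumps = list(),
                        record_dt = 0.01, total_duration = 10,
                        theta0 = 0) {
  t <- seq(0, total_duration, by = record_dt)
  angle <- theta0 + if (amplitude != 0) {
    minjerk_template(amplitude, duration, onset, t)
  } else {
    rep(0, length(t))
  }
  tau <- pmin(pmax((t - onset) / duration, 0), 1)
  speed <- if (amplitude != 0) {
    amplitude / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  } else {
    rep(0, length(t))
  }
  if (noise_sd > 0) angle <- angle + rnorm(length(t), 0, noise_sd)

  trace <- tibble::tibble(time = t, angle = angle, speed = speed)
  for (ch in c(NEURON_NAMES, AFFERENT_NAMES, "flex_emg", "ext_emg")) {
    base <- if (ch %in% AFFERENT_NAMES) -65 else -60
    v <- rep(base, length(t))
    if (!is.null(bumps[[ch]])) {
      b <- bumps[[ch]]
      for (i in seq_len(nrow(b))) {
        v <- v + b$amp[i] * exp(-((t - b$time[i])^2) / (2 * b$width[i]^2))
      }
    }
    trace[[ch]] <- v
  }
  trace$flex_tension <- rep(0, length(t))
  trace$ext_tension <- rep(0, length(t))
  trace <- trace[, c("time", TRACE_CHANNELS)]
  class(trace) <- c("spinal_trace", class(trace))
  attr(trace, "failed") <- FALSE
  attr(trace, "variant") <- "synthetic"
  trace
}

#' Gaussian bump table helper
#'
#' @param time,amp,width vectors of bump centers (s), amplitudes (mV
#'   above rest) and Gaussian sds (s).
#' @export
bump_set <- function(time, amp, width = 0.08) {
  tibble::tibble(time = time, amp = amp,
                 width = rep_len(width, length(time)))
}

#' Synthetic behavior surrogate evaluator
#'
#' A cheap deterministic stand-in for [trial_evaluator()]: maps a
#' command vector to a movement whose amplitude and speed are smooth
#' functions of the vector's first two coordinates, valid inside the
#' admissible behavior box.  Used to exercise the goal-exploration loop
#' without the simulator.
#'
#' @param n_params vector length it accepts.
#' @return `function(vector) -> one-row metrics tibble`.
#' @export
surrogate_evaluator <- function(n_params = 50) {
  function(vector) {
    stopifnot(length(vector) == n_params)
    amplitude <- 120 * vector[1]
    speed <- 400 * vector[2] * (0.25 + 0.75 * vector[1])
    duration <- if (speed > 0) 1.875 * amplitude / speed else Inf
    valid <- amplitude >= 10 && amplitude <= 110 && duration <= 2
    tibble::tibble(
      amplitude = amplitude, max_speed = speed,
      duration = duration, mse = 0, penalty_prep = 0, penalty_main = 0,
      cost = if (valid) 0.1 else 2, valid = valid,
      reasons = if (valid) "" else "surrogate",
      triphasic = speed > 150, ag1_time = NA_real_, ag1_amp = NA_real_,
      ant_time = NA_real_, ant_amp = NA_real_, ag2_time = NA_real_,
      ag2_amp = NA_real_
    )
  }
}
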