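#' Muscle spindle parameters
#'
#' The spindle is modeled as a miniature linear Hill element sharing the
#' muscle's attachments (so it is driven by the same path length), with an
#' active drive supplied by its gamma motoneuron.  Its Ia output combines a
#' tonic term proportional to the spindle serial tension (length coding)
#' and a phasic term proportional to the tension rate (velocity and
#' acceleration coding, carried by the serial spring).  A slack spindle
#' (zero tension) is silent regardless of history.
#'
#' Gains were chosen by hand so that the tonic component spans roughly
#' 20-25 mV over the joint range (strong enough for the length-coded Ia
#' signal to gate motoneuron drive on and off as the muscle shortens,
#' the mechanism that terminates movements) and a fast ramp produces an
#' onset transient exceeding the post-ramp plateau, the qualitative
#' fingerprint of primary spindle afferent recordings.
#'
#' @param muscle the host [muscle_params()] (its working range sets the
#'   spindle slack length, so the spindle is maximally unloaded at the
#'   muscle's shortest in-range length).
#' @param damping_B,parallel_stiffness_Kpe,serial_stiffness_Kse miniature
#'   Hill constants (N s/m, N/m, N/m).
#' @param max_tension cap on the gamma-driven active drive (N).
#' @param tension_gain_kT tonic gain (mV/N).
#' @param tension_rate_gain_kdT phasic gain (mV s/N).
#' @param rest_potential Ia rest potential (mV).
#' @param gamma_gain active drive per mV of suprathreshold gamma
#'   motoneuron potential (N/mV).
#' @param gamma_threshold gamma motoneuron potential below which the
#'   fusimotor drive is zero (mV).
#' @return A `spindle_params` list.
#' @export
spindle_params <- function(muscle,
                           damping_B = 2,
                           parallel_stiffness_Kpe = 25,
                           serial_stiffness_Kse = 50,
                           max_tension = 20,
                           tension_gain_kT = 15,
                           tension_rate_gain_kdT = 3.5,
                           rest_potential = -65,
                           gamma_gain = 0.05,
                           gamma_threshold = -60) {
  stopifnot(tension_gain_kT >= 0, tension_rate_gain_kdT >= 0,
            gamma_gain >= 0)
  slack <- min(muscle$length_at_angle_lo, muscle$length_at_angle_hi)
  hill <- muscle_params(
    name = paste0(muscle$name, "_spindle"),
    damping_B = damping_B,
    parallel_stiffness_Kpe = parallel_stiffness_Kpe,
    serial_stiffness_Kse = serial_stiffness_Kse,
    natural_length = slack,
    max_tension = max_tension,
    lt_width = muscle$lt_width,
    lt_resting_length = muscle$lt_resting_length,
    st_amplitude = 1, st_x_offset = 0, st_y_offset = 0,
    length_at_angle_lo = muscle$length_at_angle_lo,
    length_at_angle_hi = muscle$length_at_angle_hi,
    slack_length = slack
  )
  structure(
    list(
      hill_params = hill,
      tension_gain_kT = tension_gain_kT,
      tension_rate_gain_kdT = tension_rate_gain_kdT,
      rest_potential = rest_potential,
      gamma_gain = gamma_gain,
      gamma_threshold = gamma_threshold
    ),
    class = "spindle_params"
  )
}

# Fusimotor drive of the (single, mixed-type) gamma motoneuron.
gamma_drive <- function(gamma_potential, p) {
  p$gamma_gain * max(0, gamma_potential - p$gamma_threshold)
}

# Ia potential from spindle tension and its (clamped) derivative.
ia_potential <- function(tension, tension_deriv, p) {
  if (tension <= 0) return(p$rest_potential)
  p$rest_potential + p$tension_gain_kT * tension +
    p$tension_rate_gain_kdT * tension_deriv
}

#' Advance a muscle spindle one time step
#'
#' The spindle's internal Hill element tracks the imposed muscle length;
#' its active drive is the suprathreshold gamma motoneuron potential
#' scaled by `gamma_gain` (and capped at the spindle's `max_tension`).
#' The Ia output is `rest + kT * T + kdT * dT/dt`, clamped to rest
#' whenever the spindle is slack (T = 0).
#'
#' @param spindle_state a [muscle_state()] describing the internal element.
#' @param imposed_length muscle path length at the end of the step (m).
#' @param gamma_potential gamma motoneuron membrane potential (mV).
#' @param dt time step (s), > 0.
#' @param p a [spindle_params()] object.
#' @return A list with elements `state` (updated [muscle_state()]) and
#'   `ia` (Ia afferent potential, mV).
#' @export
spindle_step <- function(spindle_state, imposed_length, gamma_potential, dt, p) {
  stopifnot(dt > 0)
  act <- min(gamma_drive(gamma_potential, p), p$hill_params$max_tension)
  v <- (imposed_length - spindle_state$length) / dt
  f <- function(tt, ll) hill_tension_deriv(tt, ll, v, act, p$hill_params)
  l_mid <- (spindle_state$length + imposed_length) / 2
  k1 <- f(spindle_state$tension, spindle_state$length)
  k2 <- f(spindle_state$tension + dt / 2 * k1, l_mid)
  k3 <- f(spindle_state$tension + dt / 2 * k2, l_mid)
  k4 <- f(spindle_state$tension + dt * k3, imposed_length)
  tension <- max(0, spindle_state$tension + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  d_end <- f(tension, imposed_length)
  state <- muscle_state(
    length = imposed_length, length_rate = v, tension = tension,
    activation_A = act, membrane_potential = spindle_state$membrane_potential
  )
  list(state = state, ia = ia_potential(tension, d_end, p))
}

#' Golgi tendon organ parameters
#'
#' Memoryless saturating affine map from total muscle tension to the Ib
#' afferent potential.
#'
#' @param tension_gain_kB mV per newton of muscle tension.
#' @param rest_potential Ib rest potential (mV).
#' @param saturation ceiling potential (mV).
#' @export
gto_params <- function(tension_gain_kB = 0.3, rest_potential = -65,
                       saturation = -10) {
  stopifnot(tension_gain_kB >= 0, saturation > rest_potential)
  structure(
    list(tension_gain_kB = tension_gain_kB,
         rest_potential = rest_potential, saturation = saturation),
    class = "gto_params"
  )
}

#' Ib (Golgi tendon organ) output
#'
#' @param muscle_tension total muscle tension (N), non-negative.
#' @param p a [gto_params()] object.
#' @return Ib afferent potential (mV), monotone non-decreasing in tension
#'   and clamped at `saturation`.
#' @export
gto_output <- function(muscle_tension, p) {
  if (any(muscle_tension < 0)) {
    stop("muscle_tension must be non-negative", call. = FALSE)
  }
  pmin(p$rest_potential + p$tension_gain_kB * muscle_tension, p$saturation)
}
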