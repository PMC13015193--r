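#' Hill muscle parameter set
#'
#' Constructs the constant parameter block of one linear Hill muscle
#' (serial elastic element Kse, parallel elastic element Kpe, damping B,
#' active contractile element bounded by `max_tension`), together with its
#' length-tension bell, its stimulus-tension sigmoid, and the affine map
#' from elbow angle to muscle path length.
#'
#' The stimulus-tension sigmoid is
#' `amplitude / (1 + exp(k * (x_offset - v))) + y_offset`, clamped below at
#' zero, with `k = st_steepness / st_scale` per millivolt. The rescaling
#' constant `st_scale` (default 250) keeps the published steepness value
#' of 100 numerically usable on a millivolt axis while preserving two
#' anchor properties: zero force at the -60 mV rest potential and
#' `amplitude/2 + y_offset` at `v = st_x_offset`.  With the default
#' scale, activation spans roughly (-31, -10) mV of muscle membrane
#' potential, leaving a subthreshold band in which a depolarized muscle
#' produces no force.
#'
#' The length-tension factor is the inverted parabola
#' `max(0, 1 - ((L - lt_resting_length) / lt_width)^2)`; with the default
#' biceps values this spans roughly 10-90% of maximal tension over the
#' working range and 90-100% for the triceps.
#'
#' `slack_length` is the slack length of the parallel elastic element.  It
#' defaults to the muscle's longest in-range path length so that a resting
#' (inactive) muscle produces no force anywhere in the working range of the
#' joint; `natural_length` records the anatomical muscle length and is not
#' used by the dynamics.
#'
#' @param name muscle label.
#' @param damping_B damping of the contractile element (N s/m).
#' @param parallel_stiffness_Kpe,serial_stiffness_Kse spring constants (N/m).
#' @param natural_length anatomical length (m), recorded only.
#' @param max_tension cap on the active drive (N).
#' @param lt_width,lt_resting_length length-tension bell half-width and
#'   center (m).
#' @param st_amplitude,st_steepness,st_x_offset,st_y_offset,st_scale
#'   stimulus-tension sigmoid parameters (N, dimensionless, mV, N,
#'   dimensionless).
#' @param length_at_angle_lo,length_at_angle_hi path length (m) at
#'   `angle_lo` and `angle_hi` (degrees).
#' @param angle_lo,angle_hi joint angles (degrees) anchoring the affine
#'   length-angle map.
#' @param slack_length slack length of the parallel spring (m); defaults to
#'   the longer of the two endpoint lengths.
#' @return An object of class `muscle_params` (a named list).
#' @seealso [default_plant()] for the stock biceps/triceps pair.
#' @export
muscle_params <- function(name,
                          damping_B = 1,
                          parallel_stiffness_Kpe = 100,
                          serial_stiffness_Kse = 1000,
                          natural_length,
                          max_tension,
                          lt_width,
                          lt_resting_length = 0.385,
                          st_amplitude,
                          st_steepness = 100,
                          st_x_offset,
                          st_y_offset,
                          st_scale = 250,
                          length_at_angle_lo,
                          length_at_angle_hi,
                          angle_lo = 0,
                          angle_hi = 120,
                          slack_length = max(length_at_angle_lo, length_at_angle_hi)) {
  stopifnot(
    damping_B > 0, parallel_stiffness_Kpe > 0, serial_stiffness_Kse > 0,
    max_tension > 0, lt_width > 0,
    length_at_angle_lo != length_at_angle_hi,
    angle_lo != angle_hi
  )
  structure(
    list(
      name = name,
      damping_B = damping_B,
      parallel_stiffness_Kpe = parallel_stiffness_Kpe,
      serial_stiffness_Kse = serial_stiffness_Kse,
      natural_length = natural_length,
      slack_length = slack_length,
      max_tension = max_tension,
      lt_width = lt_width,
      lt_resting_length = lt_resting_length,
      st_amplitude = st_amplitude,
      st_steepness = st_steepness,
      st_x_offset = st_x_offset,
      st_y_offset = st_y_offset,
      st_scale = st_scale,
      length_at_angle_lo = length_at_angle_lo,
      length_at_angle_hi = length_at_angle_hi,
      angle_lo = angle_lo,
      angle_hi = angle_hi
    ),
    class = "muscle_params"
  )
}

#' Muscle path length at a joint angle
#'
#' Affine interpolation between the two anchor points of the length-angle
#' map; the (constant) slope is the moment arm in m/degree, signed so that
#' a flexor shortens as the elbow flexes.
#'
#' @param angle elbow angle in degrees, 0 = full extension.
#' @param muscle a [muscle_params()] object.
#' @return Path length in meters.
#' @export
muscle_length_of_angle <- function(angle, muscle) {
  if (any(angle < 0 - 1e-9 | angle > 120 + 1e-9)) {
    stop("angle must lie in [0, 120] degrees", call. = FALSE)
  }
  slope <- (muscle$length_at_angle_hi - muscle$length_at_angle_lo) /
    (muscle$angle_hi - muscle$angle_lo)
  muscle$length_at_angle_lo + slope * (angle - muscle$angle_lo)
}

#' Moment arm of a muscle (m/rad, positive magnitude)
#' @inheritParams muscle_length_of_angle
#' @export
moment_arm <- function(muscle) {
  slope <- (muscle$length_at_angle_hi - muscle$length_at_angle_lo) /
    (muscle$angle_hi - muscle$angle_lo)
  abs(slope) * 180 / pi
}

#' Stimulus-tension sigmoid
#'
#' Active drive generated by a muscle membrane potential, clamped below at
#' zero so that no force is produced at the -60 mV rest potential.
#'
#' @param v muscle membrane potential (mV).
#' @param muscle a [muscle_params()] object.
#' @return Tension (N), non-negative.
#' @export
stimulus_tension <- function(v, muscle) {
  stopifnot(all(is.finite(v)))
  k <- muscle$st_steepness / muscle$st_scale
  raw <- muscle$st_amplitude / (1 + exp(k * (muscle$st_x_offset - v))) +
    muscle$st_y_offset
  pmax(raw, 0)
}

#' Length-tension factor
#'
#' Inverted-parabola bell centered on `lt_resting_length` with half-width
#' `lt_width`, clamped to `[0, 1]`.
#'
#' @param length muscle length (m).
#' @param muscle a [muscle_params()] object.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
length_tension <- function(length, muscle) {
  stopifnot(all(length > 0))
  pmax(0, 1 - ((length - muscle$lt_resting_length) / muscle$lt_width)^2)
}

#' Active drive of a muscle
#'
#' Product of the stimulus-tension sigmoid and the length-tension factor,
#' capped at `max_tension`.
#' @inheritParams stimulus_tension
#' @param length muscle length (m).
#' @return Tension (N) in `[0, max_tension]`.
#' @export
muscle_activation <- function(v, length, muscle) {
  pmin(stimulus_tension(v, muscle) * length_tension(length, muscle),
       muscle$max_tension)
}

#' Muscle state
#'
#' @param length,length_rate muscle path length (m) and its rate (m/s).
#' @param tension serial-element tension (N).
#' @param activation_A active drive (N).
#' @param membrane_potential muscle membrane potential (mV).
#' @return A `muscle_state` list.
#' @export
muscle_state <- function(length, length_rate = 0, tension = 0,
                         activation_A = 0, membrane_potential = -60) {
  stopifnot(tension >= 0, activation_A >= 0, is.finite(membrane_potential))
  structure(
    list(length = length, length_rate = length_rate, tension = tension,
         activation_A = activation_A,
         membrane_potential = membrane_potential),
    class = "muscle_state"
  )
}

# Serial-tension derivative of the linear Hill model.  dx is stretch of the
# parallel element beyond its slack length (clamped at 0: a slack muscle
# cannot push); the derivative is clamped so tension never goes negative.
hill_tension_deriv <- function(tension, length, length_rate, activation, muscle) {
  dx <- max(0, length - muscle$slack_length)
  kse <- muscle$serial_stiffness_Kse
  kpe <- muscle$parallel_stiffness_Kpe
  b <- muscle$damping_B
  dT <- (kse / b) *
    (kpe * dx + b * length_rate - (1 + kpe / kse) * tension + activation)
  if (tension <= 0 && dT < 0) dT <- 0
  dT
}

#' Advance a Hill muscle one time step
#'
#' Integrates the linear Hill tension ODE
#' `dT/dt = (Kse/B) * (Kpe*dx + B*dx/dt - (1 + Kpe/Kse)*T + A)` with a
#' classical fourth-order Runge-Kutta step, where the active drive `A` is
#' computed from the muscle membrane potential and length via
#' [muscle_activation()].  The muscle length is externally driven (by the
#' joint kinematics); tension is clamped non-negative.
#'
#' @param state a [muscle_state()].
#' @param driven_length imposed muscle length at the end of the step (m).
#' @param dt time step (s), > 0.
#' @param muscle a [muscle_params()] object.
#' @return The updated `muscle_state`.
#' @export
hill_step <- function(state, driven_length, dt, muscle) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$tension, state$length, driven_length)))) {
    stop("non-finite muscle state", call. = FALSE)
  }
  v <- (driven_length - state$length) / dt
  act <- muscle_activation(state$membrane_potential, state$length, muscle)
  f <- function(tt, ll) hill_tension_deriv(tt, ll, v, act, muscle)
  l_mid <- (state$length + driven_length) / 2
  k1 <- f(state$tension, state$length)
  k2 <- f(state$tension + dt / 2 * k1, l_mid)
  k3 <- f(state$tension + dt / 2 * k2, l_mid)
  k4 <- f(state$tension + dt * k3, driven_length)
  tension <- state$tension + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  muscle_state(
    length = driven_length,
    length_rate = v,
    tension = max(0, tension),
    activation_A = act,
    membrane_potential = state$membrane_potential
  )
}

#' Segment specification
#' @param name label.
#' @param length segment length (m).
#' @param mass segment mass (kg).
#' @export
segment_spec <- function(name, length, mass) {
  stopifnot(length > 0, mass > 0)
  structure(list(name = name, length = length, mass = mass),
            class = "segment_spec")
}

#' Forearm + hand moment of inertia about the elbow
#'
#' Forearm modeled as a uniform rod rotating about its proximal end
#' (`m L^2 / 3`), hand as a point mass at forearm length plus half the hand
#' length.
#'
#' @param forearm,hand [segment_spec()] objects.
#' @return Moment of inertia (kg m^2).
#' @export
limb_inertia <- function(forearm, hand) {
  forearm$mass * forearm$length^2 / 3 +
    hand$mass * (forearm$length + hand$length / 2)^2
}

#' Joint state
#' @param angle elbow angle (degrees, 0 = full extension).
#' @param angular_velocity degrees per second.
#' @param inertia moment of inertia (kg m^2).
#' @export
joint_state <- function(angle = 0, angular_velocity = 0, inertia) {
  stopifnot(angle >= 0, angle <= 120, inertia > 0)
  structure(list(angle = angle, angular_velocity = angular_velocity,
                 inertia = inertia),
            class = "joint_state")
}

#' Advance the elbow joint one time step
#'
#' Angular acceleration is
#' `(r_flex * T_flex - r_ext * T_ext - b_joint * omega) / I` (no gravity
#' torque); the angle is clipped to the hard stops at 0 and 120 degrees
#' with the velocity zeroed against the stop.
#'
#' @param joint a [joint_state()].
#' @param flexor,extensor [muscle_state()] objects supplying tensions (N).
#' @param dt time step (s).
#' @param r_flex,r_ext moment arms (m/rad).
#' @param b_joint viscous joint damping (N m s/rad).
#' @return Updated `joint_state`.
#' @export
joint_step <- function(joint, flexor, extensor, dt,
                       r_flex, r_ext, b_joint = 0.25) {
  stopifnot(dt > 0)
  omega <- joint$angular_velocity * pi / 180       # rad/s
  torque <- r_flex * flexor$tension - r_ext * extensor$tension -
    b_joint * omega
  alpha <- torque / joint$inertia                  # rad/s^2
  omega_new <- omega + alpha * dt
  theta_new <- joint$angle + (omega + omega_new) / 2 * dt * 180 / pi
  if (theta_new <= 0) {
    theta_new <- 0
    if (omega_new < 0) omega_new <- 0
  } else if (theta_new >= 120) {
    theta_new <- 120
    if (omega_new > 0) omega_new <- 0
  }
  joint_state(theta_new, omega_new * 180 / pi, joint$inertia)
}

#' Default musculoskeletal plant
#'
#' The stock elbow plant: segment table (humerus/forearm/hand), the
#' biceps/triceps Hill parameter pair, joint inertia and damping, the
#' motoneuron-to-muscle drive synapse, and the spindle/GTO afferent
#' parameter blocks.
#'
#' @param b_joint joint viscous damping (N m s/rad).
#' @param drive_gmax conductance of the fixed alpha-MN-to-muscle synapse
#'   (relative to the unit leak conductance).
#' @return A `plant_config` list with elements `segments`, `flexor`,
#'   `extensor`, `joint`, `drive`, `spindle_flex`, `spindle_ext`,
#'   `gto_flex`, `gto_ext`.
#' @export
default_plant <- function(b_joint = 0.15, drive_gmax = 10) {
  forearm <- segment_spec("forearm", 0.2831808226, 0.802)
  hand <- segment_spec("hand", 0.19321, 0.966)
  humerus <- segment_spec("humerus", 0.3370911395, 1.164)
  biceps <- muscle_params(
    name = "biceps",
    natural_length = 0.33898, max_tension = 400,
    lt_width = 0.14, lt_resting_length = 0.385,
    st_amplitude = 400, st_x_offset = -20, st_y_offset = -4.5,
    length_at_angle_lo = 0.34, length_at_angle_hi = 0.25
  )
  triceps <- muscle_params(
    name = "triceps",
    natural_length = 0.2725, max_tension = 300,
    lt_width = 0.35, lt_resting_length = 0.385,
    st_amplitude = 300, st_x_offset = -30, st_y_offset = -4,
    length_at_angle_lo = 0.275, length_at_angle_hi = 0.345
  )
  structure(
    list(
      segments = list(humerus = humerus, forearm = forearm, hand = hand),
      flexor = biceps,
      extensor = triceps,
      joint = list(
        inertia = limb_inertia(forearm, hand),
        b_joint = b_joint,
        angle_min = 0, angle_max = 120
      ),
      drive = list(
        gmax = drive_gmax, pre_threshold = -60, pre_saturation = -20,
        reversal = -10, rest = -60, tau = 0.01
      ),
      spindle_flex = spindle_params(muscle = biceps),
      spindle_ext = spindle_params(muscle = triceps),
      gto_flex = gto_params(),
      gto_ext = gto_params()
    ),
    class = "plant_config"
  )
}
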