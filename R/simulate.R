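#' Simulation configuration
#'
#' @param physics_dt integrator step (s); fixed-step RK4.
#' @param record_dt recording interval (s), a multiple of `physics_dt`;
#'   the default 10 ms matches the cost-function sampling.
#' @param duration trial length (s); SET at 1 s, GO at 5 s, end at 10 s.
#' @param rng_seed optional integer recorded with the trace (the trial
#'   itself is deterministic).
#' @param initial_angle starting elbow angle (degrees).
#' @export
sim_config <- function(physics_dt = 0.001, record_dt = 0.01, duration = 10,
                       rng_seed = NULL, initial_angle = 0) {
  stopifnot(physics_dt > 0, physics_dt <= record_dt,
            abs(record_dt / physics_dt - round(record_dt / physics_dt)) < 1e-9,
            duration > 0, initial_angle >= 0, initial_angle <= 120)
  structure(
    list(physics_dt = physics_dt, record_dt = record_dt, duration = duration,
         rng_seed = rng_seed, initial_angle = initial_angle),
    class = "sim_config"
  )
}

#' Lesion specification
#'
#' @param clamped_neurons named numeric vector: node label -> clamp
#'   potential (mV); the node's output is held at that value for the whole
#'   trial (e.g. `c(Flx1a = -65)`).
#' @param suppressed_synapses list of `c(pre, post)` label pairs whose
#'   conductance is forced to zero.  A pair absent from the topology is a
#'   no-op with a warning.
#' @export
lesion_spec <- function(clamped_neurons = NULL, suppressed_synapses = NULL) {
  if (!is.null(clamped_neurons)) {
    stopifnot(is.numeric(clamped_neurons), !is.null(names(clamped_neurons)))
    bad <- setdiff(names(clamped_neurons), ALL_NODE_NAMES)
    if (length(bad)) {
      stop("unknown node(s) in lesion: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(clamped_neurons = clamped_neurons,
                 suppressed_synapses = suppressed_synapses),
            class = "lesion_spec")
}

TRACE_CHANNELS <- c("angle", "speed", NEURON_NAMES, AFFERENT_NAMES,
                    "flex_emg", "ext_emg", "flex_tension", "ext_tension")

# Flatten configs into the parameter bundle shared by the compiled and
# reference engines.
build_engine_pars <- function(vector, topology, plant, sim, lesion,
                              ranges, go_include_alpha) {
  schedule <- decode(vector, topology, ranges = ranges,
                     go_include_alpha = go_include_alpha)
  iset <- setNames(rep(0, 12), NEURON_NAMES)
  iset[names(schedule$set_current)] <- schedule$set_current
  igo <- setNames(rep(0, 12), NEURON_NAMES)
  igo[names(schedule$go_current)] <- schedule$go_current

  syn <- topology$synapses
  suppressed <- rep(0L, nrow(syn))
  clamp_mask <- rep(0L, 16)
  clamp_value <- rep(0, 16)
  if (!is.null(lesion)) {
    if (!is.null(lesion$clamped_neurons)) {
      idx <- match(names(lesion$clamped_neurons), ALL_NODE_NAMES)
      clamp_mask[idx] <- 1L
      clamp_value[idx] <- lesion$clamped_neurons
    }
    for (pair in lesion$suppressed_synapses) {
      hit <- which(syn$pre == pair[1] & syn$post == pair[2])
      if (!length(hit)) {
        warning(sprintf("synapse %s->%s not in topology '%s'; lesion is a no-op",
                        pair[1], pair[2], topology$variant), call. = FALSE)
      } else {
        suppressed[hit] <- 1L
      }
    }
  }

  two <- function(f, e) c(f, e)
  flx <- plant$flexor; ext <- plant$extensor
  spf <- plant$spindle_flex; spe <- plant$spindle_ext
  slope <- function(m) (m$length_at_angle_hi - m$length_at_angle_lo) /
    (m$angle_hi - m$angle_lo)
  l_slope <- two(slope(flx), slope(ext))
  l_int <- two(flx$length_at_angle_lo - slope(flx) * flx$angle_lo,
               ext$length_at_angle_lo - slope(ext) * ext$angle_lo)

  theta0 <- sim$initial_angle
  sp_steady <- function(sp, m, intercept, slp) {
    L0 <- intercept + slp * theta0
    h <- sp$hill_params
    h$parallel_stiffness_Kpe * max(0, L0 - h$slack_length) /
      (1 + h$parallel_stiffness_Kpe / h$serial_stiffness_Kse)
  }
  y0 <- c(rep(-60, 12), rep(plant$drive$rest, 2), 0, 0,
          sp_steady(spf, flx, l_int[1], l_slope[1]),
          sp_steady(spe, ext, l_int[2], l_slope[2]),
          theta0, 0)
  y0[seq_len(12)][clamp_mask[seq_len(12)] == 1L] <-
    clamp_value[seq_len(12)][clamp_mask[seq_len(12)] == 1L]

  list(
    dt = sim$physics_dt,
    n_steps = as.integer(round(sim$duration / sim$physics_dt)),
    record_stride = as.integer(round(sim$record_dt / sim$physics_dt)),
    set_time = schedule$set_time, go_time = schedule$go_time,
    iset = unname(iset), igo = unname(igo),
    rest = rep(-60, 12), tau = rep(0.01, 12), gl = rep(1, 12),
    clamp_mask = clamp_mask, clamp_value = clamp_value,
    pre = match(syn$pre, ALL_NODE_NAMES) - 1L,
    post = match(syn$post, ALL_NODE_NAMES) - 1L,
    suppressed = suppressed,
    gmax = syn$max_conductance, thr = syn$pre_threshold,
    sat = syn$pre_saturation, erev = syn$reversal,
    gain = unname(schedule$gain),
    l_int = l_int, l_slope = l_slope,
    mB = two(flx$damping_B, ext$damping_B),
    mKpe = two(flx$parallel_stiffness_Kpe, ext$parallel_stiffness_Kpe),
    mKse = two(flx$serial_stiffness_Kse, ext$serial_stiffness_Kse),
    mslack = two(flx$slack_length, ext$slack_length),
    mmaxT = two(flx$max_tension, ext$max_tension),
    lt_w = two(flx$lt_width, ext$lt_width),
    lt_c = two(flx$lt_resting_length, ext$lt_resting_length),
    st_amp = two(flx$st_amplitude, ext$st_amplitude),
    st_k = two(flx$st_steepness / flx$st_scale,
               ext$st_steepness / ext$st_scale),
    st_x0 = two(flx$st_x_offset, ext$st_x_offset),
    st_y0 = two(flx$st_y_offset, ext$st_y_offset),
    sB = two(spf$hill_params$damping_B, spe$hill_params$damping_B),
    sKpe = two(spf$hill_params$parallel_stiffness_Kpe,
               spe$hill_params$parallel_stiffness_Kpe),
    sKse = two(spf$hill_params$serial_stiffness_Kse,
               spe$hill_params$serial_stiffness_Kse),
    sslack = two(spf$hill_params$slack_length, spe$hill_params$slack_length),
    smaxT = two(spf$hill_params$max_tension, spe$hill_params$max_tension),
    kT = two(spf$tension_gain_kT, spe$tension_gain_kT),
    kdT = two(spf$tension_rate_gain_kdT, spe$tension_rate_gain_kdT),
    ia_rest = two(spf$rest_potential, spe$rest_potential),
    g_gain = two(spf$gamma_gain, spe$gamma_gain),
    g_thr = two(spf$gamma_threshold, spe$gamma_threshold),
    kB = two(plant$gto_flex$tension_gain_kB, plant$gto_ext$tension_gain_kB),
    ib_rest = two(plant$gto_flex$rest_potential, plant$gto_ext$rest_potential),
    ib_sat = two(plant$gto_flex$saturation, plant$gto_ext$saturation),
    d_gmax = plant$drive$gmax, d_thr = plant$drive$pre_threshold,
    d_sat = plant$drive$pre_saturation, d_erev = plant$drive$reversal,
    d_rest = plant$drive$rest, d_tau = plant$drive$tau,
    inertia = plant$joint$inertia, b_joint = plant$joint$b_joint,
    r_flex = abs(l_slope[1]) * 180 / pi,
    r_ext = abs(l_slope[2]) * 180 / pi,
    angle_min = plant$joint$angle_min, angle_max = plant$joint$angle_max,
    y0 = y0
  )
}

# Pure-R twin of the compiled integrator; slow, used as a cross-check.
sim_core_reference <- function(p) {
  hill_d <- function(T, dx, v, A, B, Kpe, Kse) {
    dT <- (Kse / B) * (Kpe * dx + B * v - (1 + Kpe / Kse) * T + A)
    if (T <= 0 && dT < 0) dT <- 0
    dT
  }
  cmask <- p$clamp_mask; cval <- p$clamp_value
  deriv <- function(t, y, want_aff = FALSE) {
    set_on <- t >= p$set_time - 1e-12
    go_on <- t >= p$go_time - 1e-12
    theta <- y[19]; omega <- y[20]
    L <- p$l_int + p$l_slope * theta
    dL <- p$l_slope * omega
    dTsp <- ia <- numeric(2)
    for (m in 1:2) {
      vg <- if (cmask[2 + m]) cval[2 + m] else y[2 + m]
      act <- min(p$g_gain[m] * max(0, vg - p$g_thr[m]), p$smaxT[m])
      dx <- max(0, L[m] - p$sslack[m])
      T <- y[16 + m]
      dTsp[m] <- hill_d(T, dx, dL[m], act, p$sB[m], p$sKpe[m], p$sKse[m])
      ia[m] <- if (T <= 0) p$ia_rest[m] else
        p$ia_rest[m] + p$kT[m] * T + p$kdT[m] * dTsp[m]
    }
    ib <- pmin(p$ib_rest + p$kB * pmax(0, y[15:16]), p$ib_sat)
    P <- c(ifelse(cmask[1:12] == 1, cval[1:12], y[1:12]),
           ifelse(cmask[13:16] == 1, cval[13:16], c(ia, ib)))
    G <- GE <- numeric(12)
    if (set_on) {
      frac <- pmin(pmax((P[p$pre + 1] - p$thr) / (p$sat - p$thr), 0), 1)
      g <- ifelse(p$suppressed == 1, 0, p$gain * p$gmax * frac)
      for (s in which(g > 0)) {
        G[p$post[s] + 1] <- G[p$post[s] + 1] + g[s]
        GE[p$post[s] + 1] <- GE[p$post[s] + 1] + g[s] * p$erev[s]
      }
    }
    dy <- numeric(20)
    I <- (if (set_on) p$iset else 0) + (if (go_on) p$igo else 0)
    dy[1:12] <- (p$gl * (p$rest - y[1:12]) + GE - G * y[1:12] + I) /
      (p$tau * p$gl)
    dy[1:12][cmask[1:12] == 1] <- 0
    for (m in 1:2) {
      frac <- min(max((P[m] - p$d_thr) / (p$d_sat - p$d_thr), 0), 1)
      g <- p$d_gmax * frac
      dy[12 + m] <- ((p$d_rest - y[12 + m]) + g * (p$d_erev - y[12 + m])) /
        p$d_tau
    }
    for (m in 1:2) {
      stv <- max(0, p$st_amp[m] /
                   (1 + exp(p$st_k[m] * (p$st_x0[m] - y[12 + m]))) +
                   p$st_y0[m])
      ltf <- max(0, 1 - ((L[m] - p$lt_c[m]) / p$lt_w[m])^2)
      A <- min(stv * ltf, p$mmaxT[m])
      dx <- max(0, L[m] - p$mslack[m])
      dy[14 + m] <- hill_d(y[14 + m], dx, dL[m], A,
                           p$mB[m], p$mKpe[m], p$mKse[m])
    }
    dy[17:18] <- dTsp
    torque <- p$r_flex * max(0, y[15]) - p$r_ext * max(0, y[16]) -
      p$b_joint * omega * pi / 180
    dy[19] <- omega
    dy[20] <- torque / p$inertia * 180 / pi
    if (want_aff) list(dy = dy, aff = P[13:16]) else dy
  }

  y <- p$y0
  n_rec <- p$n_steps %/% p$record_stride + 1
  out <- matrix(NA_real_, n_rec, 22)
  time <- numeric(n_rec)
  ok <- TRUE
  rec <- 1
  dt <- p$dt
  for (step in 0:p$n_steps) {
    t <- step * dt
    if (step %% p$record_stride == 0) {
      da <- deriv(t, y, want_aff = TRUE)
      time[rec] <- t
      out[rec, ] <- c(y[19], y[20],
                      ifelse(cmask[1:12] == 1, cval[1:12], y[1:12]),
                      da$aff, y[13], y[14], max(0, y[15]), max(0, y[16]))
      rec <- rec + 1
    }
    if (step == p$n_steps) break
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[1:12][cmask[1:12] == 1] <- cval[1:12][cmask[1:12] == 1]
    y[15:18] <- pmax(0, y[15:18])
    if (y[19] <= p$angle_min) {
      y[19] <- p$angle_min
      if (y[20] < 0) y[20] <- 0
    } else if (y[19] >= p$angle_max) {
      y[19] <- p$angle_max
      if (y[20] > 0) y[20] <- 0
    }
    if (any(!is.finite(y))) { ok <- FALSE; break }
  }
  list(time = time, channels = out, ok = ok, n_recorded = rec - 1)
}

#' Run one closed-loop trial
#'
#' Integrates plant, afferents and network under the SET/GO schedule
#' decoded from `vector`, optionally with lesions (clamped nodes,
#' suppressed synapses), and returns the recorded trace.  Deterministic:
#' identical inputs give bit-identical traces.
#'
#' @param vector normalized command vector (see [command_vector()]).
#' @param topology a [build_topology()] object.
#' @param plant a [default_plant()]-style config.
#' @param sim a [sim_config()].
#' @param lesion optional [lesion_spec()].
#' @param ranges a [command_ranges()].
#' @param go_include_alpha see [decode()].
#' @param engine `"compiled"` (Rcpp RK4 core) or `"reference"` (pure-R
#'   twin used for cross-checking).
#' @return A `spinal_trace` tibble with one row per recorded sample
#'   (default 1001 rows at 10 ms) and columns `time`, `angle`, `speed`,
#'   the 12 neuron potentials, the 4 afferent potentials, `flex_emg`,
#'   `ext_emg` (muscle membrane potentials; the model's EMG envelopes) and
#'   the two muscle tensions.  A numerically unstable trial is returned
#'   truncated with `attr(, "failed") = TRUE` rather than as an error.
#' @export
run_trial <- function(vector, topology, plant = default_plant(),
                      sim = sim_config(), lesion = NULL,
                      ranges = command_ranges(), go_include_alpha = FALSE,
                      engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  pars <- build_engine_pars(vector, topology, plant, sim, lesion,
                            ranges, go_include_alpha)
  res <- if (engine == "compiled") sim_core(pars) else
    sim_core_reference(pars)
  n <- if (res$ok) nrow(res$channels) else max(1, res$n_recorded)
  ch <- res$channels[seq_len(n), , drop = FALSE]
  colnames(ch) <- TRACE_CHANNELS
  trace <- tibble::as_tibble(as.data.frame(ch))
  trace <- tibble::add_column(trace, time = res$time[seq_len(n)],
                              .before = 1)
  class(trace) <- c("spinal_trace", class(trace))
  attr(trace, "failed") <- !res$ok
  attr(trace, "variant") <- topology$variant
  attr(trace, "sim") <- sim
  trace
}
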