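# Minimum-jerk position profile p(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5.
minjerk_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Fraction of template duration between the 5% and 95% amplitude points;
# the profile is symmetric so the window is D * (1 - 2 * tau05).
minjerk_window_fraction <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tau05 <- uniroot(function(x) minjerk_profile(x) - 0.05,
                       c(1e-6, 0.5), tol = 1e-12)$root
      cache <<- 1 - 2 * tau05
    }
    cache
  }
})

#' Minimum-jerk template
#'
#' `theta(t) = A * (10 tau^3 - 15 tau^4 + 6 tau^5)` with
#' `tau = clip((t - onset)/duration, 0, 1)`.  Peak speed is
#' `1.875 * A / duration`, reached at `tau = 0.5`.
#'
#' @param amplitude movement amplitude (degrees).
#' @param duration template duration (s), > 0.
#' @param onset movement onset time (s).
#' @param t evaluation times (s).
#' @return Angles (degrees) relative to the starting angle.
#' @export
minjerk_template <- function(amplitude, duration, onset, t) {
  stopifnot(duration > 0)
  amplitude * minjerk_profile((t - onset) / duration)
}

#' Fit a minimum-jerk template to a recorded movement
#'
#' The movement amplitude is measured as the final plateau (mean over the
#' last half second) minus the trial's initial angle (mean over the quiet
#' pre-SET first half second); the template onset and duration are then
#' found by a coarse grid search refined with box-constrained
#' optimization, minimizing the mean squared error between trace and
#' template over `t` in `[2, 10]` s.  The template is flat at the
#' *initial* angle before onset, so any drift of the elbow during the
#' preparatory phase is charged in full to the tracking error.
#'
#' @param trace a [run_trial()] trace (needs `time` and `angle` columns
#'   spanning `[0, 10]` s).
#' @param go_time earliest admissible onset (s).
#' @return A `minjerk_fit` object: `amplitude` (deg), `duration`
#'   (template duration, s), `duration_5_95` (time from 5% to 95% of
#'   amplitude, the movement-duration measure used for validity, s),
#'   `onset_time`, `mse` (deg^2), `wrong_direction`, `theta0`, and
#'   `desired_trajectory` aligned with the trace rows.
#' @export
fit_minjerk <- function(trace, go_time = 5) {
  t <- trace$time
  ang <- trace$angle
  stopifnot(max(t) >= go_time + 1)
  t_end <- max(t)
  theta0 <- mean(ang[t <= 0.5])          # quiet pre-SET baseline
  plateau <- mean(ang[t >= t_end - 0.5])
  amplitude <- plateau - theta0
  win <- t >= 2
  tw <- t[win]; aw <- ang[win]
  mse_of <- function(onset, dur) {
    mean((aw - (theta0 + minjerk_template(amplitude, dur, onset, tw)))^2)
  }
  if (abs(amplitude) < 1e-9) {
    return(structure(
      list(amplitude = amplitude, duration = NA_real_,
           duration_5_95 = NA_real_, onset_time = NA_real_,
           mse = mean((aw - theta0)^2), wrong_direction = amplitude < 0,
           theta0 = theta0,
           desired_trajectory = rep(theta0, length(t))),
      class = "minjerk_fit"
    ))
  }
  grid <- expand.grid(onset = seq(go_time, min(go_time + 2, t_end - 0.5),
                                  by = 0.1),
                      dur = seq(0.1, 3.4, by = 0.15))
  grid$mse <- mapply(mse_of, grid$onset, grid$dur)
  best <- grid[which.min(grid$mse), ]
  opt <- optim(
    c(best$onset, best$dur),
    function(par) mse_of(par[1], par[2]),
    method = "L-BFGS-B",
    lower = c(go_time, 0.02), upper = c(t_end - 0.25, 5)
  )
  onset <- opt$par[1]; dur <- opt$par[2]
  structure(
    list(
      amplitude = amplitude, duration = dur,
      duration_5_95 = dur * minjerk_window_fraction(),
      onset_time = onset, mse = opt$value,
      wrong_direction = amplitude < 0, theta0 = theta0,
      desired_trajectory = theta0 +
        minjerk_template(amplitude, dur, onset, t)
    ),
    class = "minjerk_fit"
  )
}

#' @export
print.minjerk_fit <- function(x, ...) {
  cat(sprintf(
    "<minjerk_fit> amplitude %.2f deg, duration %.3f s (5-95%%: %.3f s), onset %.3f s, mse %.4g deg^2\n",
    x$amplitude, x$duration, x$duration_5_95, x$onset_time, x$mse))
  invisible(x)
}

#' Co-contraction penalty over a time window
#'
#' Time-averaged product of the suprathreshold parts of the two
#' motoneuron potentials, scaled by `coeff`:
#' `coeff * mean(max(0, Vflex - Vthr) * max(0, Vext - Vthr))`.  It is
#' positive only when both motoneurons are simultaneously above
#' threshold; each factor is clamped at zero below `v_thr` so that two
#' silent (hyperpolarized) motoneurons are not penalized.
#'
#' @param flex_mn,ext_mn motoneuron potential series (mV).
#' @param times sample times (s).
#' @param window `c(start, end)` in seconds.
#' @param coeff scale factor (100 for both the preparatory and the
#'   maintained-position windows).
#' @param v_thr threshold (mV).
#' @export
cocontraction_penalty <- function(flex_mn, ext_mn, times, window,
                                  coeff = 100, v_thr = -60) {
  sel <- times >= window[1] & times <= window[2]
  stopifnot(any(sel))
  coeff * mean(pmax(0, flex_mn[sel] - v_thr) * pmax(0, ext_mn[sel] - v_thr))
}

#' Movement cost
#'
#' Tracking term (mean squared error between the elbow angle and the
#' desired trajectory over `t` in `[2, 10]` s at the recording rate, where
#' the desired angle is the starting angle until template onset and the
#' fitted minimum-jerk template afterwards) plus the two co-contraction
#' penalties (preparatory window `[2, 5]` s, maintained-position window
#' `[7, 10]` s, both with coefficient 100).  A movement is valid when the
#' total cost is below 1.
#'
#' @param trace a [run_trial()] trace.
#' @param fit a [fit_minjerk()] object for the same trace.
#' @param coeff penalty coefficient.
#' @param v_thr co-contraction threshold (mV).
#' @return A `cost_breakdown` list: `tracking_term`, `penalty_prep`,
#'   `penalty_main`, `total_cost`.
#' @export
cost <- function(trace, fit, coeff = 100, v_thr = -60) {
  sel <- trace$time >= 2
  tracking <- mean((trace$angle[sel] - fit$desired_trajectory[sel])^2)
  prep <- cocontraction_penalty(trace$FlxAlpha, trace$ExtAlpha, trace$time,
                                c(2, 5), coeff, v_thr)
  main <- cocontraction_penalty(trace$FlxAlpha, trace$ExtAlpha, trace$time,
                                c(7, 10), coeff, v_thr)
  structure(
    list(tracking_term = tracking, penalty_prep = prep, penalty_main = main,
         total_cost = tracking + prep + main,
         coeff = coeff, v_thr = v_thr),
    class = "cost_breakdown"
  )
}

#' Detect peaks of an EMG-like series
#'
#' Every local maximum strictly above the baseline is reported together
#' with the minima separating consecutive maxima.  Plateaus (runs of
#' exactly equal values higher than both neighbors) yield a single peak
#' at the plateau center.  Even the smallest suprabaseline peaks are
#' reported; series are expected to start and end at baseline.
#'
#' @param values series (mV).
#' @param times sample times (s); defaults to the sample index.
#' @param baseline resting level (mV); maxima at or below it are ignored.
#' @return A `peak_set` list with tibbles `peaks` (`time`, `value`) and
#'   `minima` (`time`, `value`, one row between each pair of consecutive
#'   peaks).
#' @export
detect_peaks <- function(values, times = seq_along(values), baseline = -60) {
  stopifnot(length(values) == length(times))
  r <- rle(values)
  n_runs <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  peak_idx <- integer(0)
  for (i in seq_len(n_runs)) {
    if (r$values[i] <= baseline) next
    left_ok <- i > 1 && r$values[i - 1] < r$values[i]
    right_ok <- i < n_runs && r$values[i + 1] < r$values[i]
    if (left_ok && right_ok) {
      center <- (run_start[i] + run_end[i]) %/% 2
      peak_idx <- c(peak_idx, center)
    }
  }
  peaks <- tibble::tibble(time = times[peak_idx], value = values[peak_idx])
  minima <- tibble::tibble(time = numeric(0), value = numeric(0))
  if (length(peak_idx) >= 2) {
    for (k in seq_len(length(peak_idx) - 1)) {
      seg <- seq(peak_idx[k], peak_idx[k + 1])
      vmin <- min(values[seg])
      lows <- seg[values[seg] == vmin]
      center <- lows[(length(lows) + 1) %/% 2]
      minima <- dplyr::bind_rows(
        minima, tibble::tibble(time = times[center], value = vmin))
    }
  }
  structure(list(peaks = peaks, minima = minima, baseline = baseline),
            class = "peak_set")
}

#' Classify a triphasic pattern from agonist/antagonist peak sets
#'
#' Triphasic if and only if the agonist (flexor) shows at least two peaks
#' and at least one antagonist (extensor) peak lies strictly between the
#' first two agonist peak times.  AG1/AG2 are the first two flexor peaks;
#' ANT is the largest extensor peak between them.  A silent period
#' between AG1 and AG2 (flexor returning to baseline) is reported but not
#' required.
#'
#' @param flexor_peaks,extensor_peaks [detect_peaks()] results.
#' @param silent_tol how close to baseline (mV) the inter-peak flexor
#'   minimum must come to count as a silent period.
#' @return A `triphasic_label` list: `is_triphasic`, `ag1`, `ag2`, `ant`
#'   (each `NULL` or a one-row tibble), `silent_period`,
#'   `n_flexor_peaks`, `n_extensor_peaks`.
#' @export
classify_triphasic <- function(flexor_peaks, extensor_peaks,
                               silent_tol = 0.5) {
  fp <- flexor_peaks$peaks
  ep <- extensor_peaks$peaks
  out <- list(is_triphasic = FALSE, ag1 = NULL, ag2 = NULL, ant = NULL,
              silent_period = NA,
              n_flexor_peaks = nrow(fp), n_extensor_peaks = nrow(ep))
  if (nrow(fp) >= 2) {
    fp <- fp[order(fp$time), ]
    ag1 <- fp[1, ]; ag2 <- fp[2, ]
    between <- ep[ep$time > ag1$time & ep$time < ag2$time, ]
    if (nrow(between) >= 1) {
      ant <- between[which.max(between$value), ]
      out$is_triphasic <- TRUE
      out$ag1 <- ag1; out$ag2 <- ag2; out$ant <- ant
      mins <- flexor_peaks$minima
      gap <- mins[mins$time > ag1$time & mins$time < ag2$time, ]
      out$silent_period <- nrow(gap) > 0 &&
        min(gap$value) <= flexor_peaks$baseline + silent_tol
    }
  }
  structure(out, class = "triphasic_label")
}

#' Score one trial
#'
#' Composes [fit_minjerk()], [cost()], [detect_peaks()] on the two muscle
#' EMG envelopes and [classify_triphasic()], and applies the validity
#' rules: total cost below 1, amplitude within 10-110 degrees, movement
#' duration (5-95% of amplitude) at most 2 s, flexion direction, and a
#' numerically stable trial.  Co-contraction outside the movement phase
#' is rejected through the cost penalties.
#'
#' @param trace a [run_trial()] trace.
#' @param go_time movement trigger time (s).
#' @return A one-row tibble: `amplitude`, `max_speed`, `duration`, `mse`,
#'   `penalty_prep`, `penalty_main`, `cost`, `valid`, `reasons`
#'   (comma-separated labels, empty when valid), `triphasic`,
#'   `ag1_time`, `ag1_amp`, `ant_time`, `ant_amp`, `ag2_time`, `ag2_amp`
#'   (peak times in s, amplitudes in mV above the -60 mV baseline, `NA`
#'   when not triphasic).
#' @export
evaluate_movement <- function(trace, go_time = 5) {
  empty <- tibble::tibble(
    amplitude = NA_real_, max_speed = NA_real_, duration = NA_real_,
    mse = NA_real_, penalty_prep = NA_real_, penalty_main = NA_real_,
    cost = Inf, valid = FALSE, reasons = "unstable", triphasic = FALSE,
    ag1_time = NA_real_, ag1_amp = NA_real_, ant_time = NA_real_,
    ant_amp = NA_real_, ag2_time = NA_real_, ag2_amp = NA_real_
  )
  if (isTRUE(attr(trace, "failed"))) return(empty)
  fit <- fit_minjerk(trace, go_time = go_time)
  cb <- cost(trace, fit)
  # peaks are read after the SET transients have settled (t >= 2 s); in a
  # valid movement the EMG envelopes are at baseline outside the movement
  sel <- trace$time >= 2
  fpk <- detect_peaks(trace$flex_emg[sel], trace$time[sel])
  epk <- detect_peaks(trace$ext_emg[sel], trace$time[sel])
  tri <- classify_triphasic(fpk, epk)
  reasons <- character(0)
  if (!is.finite(cb$total_cost) || cb$total_cost >= 1) {
    reasons <- c(reasons, "cost")
  }
  if (fit$wrong_direction) reasons <- c(reasons, "wrong-direction")
  if (is.na(fit$amplitude) || fit$amplitude < 10 || fit$amplitude > 110) {
    reasons <- c(reasons, "amplitude-range")
  }
  if (!is.na(fit$duration_5_95) && fit$duration_5_95 > 2) {
    reasons <- c(reasons, "too-slow")
  }
  base <- -60
  tibble::tibble(
    amplitude = fit$amplitude,
    max_speed = max(trace$speed[trace$time >= go_time]),
    duration = fit$duration_5_95,
    mse = fit$mse,
    penalty_prep = cb$penalty_prep,
    penalty_main = cb$penalty_main,
    cost = cb$total_cost,
    valid = length(reasons) == 0,
    reasons = paste(reasons, collapse = ","),
    triphasic = tri$is_triphasic,
    ag1_time = if (tri$is_triphasic) tri$ag1$time else NA_real_,
    ag1_amp = if (tri$is_triphasic) tri$ag1$value - base else NA_real_,
    ant_time = if (tri$is_triphasic) tri$ant$time else NA_real_,
    ant_amp = if (tri$is_triphasic) tri$ant$value - base else NA_real_,
    ag2_time = if (tri$is_triphasic) tri$ag2$time else NA_real_,
    ag2_amp = if (tri$is_triphasic) tri$ag2$value - base else NA_real_
  )
}
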