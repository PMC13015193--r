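#' Tidy a minimum-jerk fit
#'
#' @param x a [fit_minjerk()] object.
#' @param ... unused.
#' @return A tibble with one row per fitted quantity (`term`,
#'   `estimate`).
#' @export
tidy.minjerk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "duration", "duration_5_95", "onset_time"),
    estimate = c(x$amplitude, x$duration, x$duration_5_95, x$onset_time)
  )
}

#' One-row summary of a minimum-jerk fit
#' @inheritParams tidy.minjerk_fit
#' @export
glance.minjerk_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, duration = x$duration,
                 duration_5_95 = x$duration_5_95,
                 onset_time = x$onset_time, mse = x$mse,
                 wrong_direction = x$wrong_direction)
}

#' Tidy a peak set
#' @param x a [detect_peaks()] result.
#' @param ... unused.
#' @return The peak tibble (`time`, `value`).
#' @export
tidy.peak_set <- function(x, ...) x$peaks

#' Tidy a triphasic label
#' @param x a [classify_triphasic()] result.
#' @param ... unused.
#' @export
tidy.triphasic_label <- function(x, ...) {
  g <- function(p, f) if (is.null(p)) NA_real_ else p[[f]]
  tibble::tibble(
    is_triphasic = x$is_triphasic,
    ag1_time = g(x$ag1, "time"), ag1_value = g(x$ag1, "value"),
    ant_time = g(x$ant, "time"), ant_value = g(x$ant, "value"),
    ag2_time = g(x$ag2, "time"), ag2_value = g(x$ag2, "value"),
    silent_period = x$silent_period,
    n_flexor_peaks = x$n_flexor_peaks,
    n_extensor_peaks = x$n_extensor_peaks
  )
}

#' Tidy a cost breakdown
#' @param x a [cost()] result.
#' @param ... unused.
#' @export
tidy.cost_breakdown <- function(x, ...) {
  tibble::tibble(term = c("tracking", "penalty_prep", "penalty_main"),
                 value = c(x$tracking_term, x$penalty_prep, x$penalty_main))
}

#' Archive of a goal-exploration run
#' @param x a [run_gep()] result.
#' @param ... unused.
#' @export
tidy.gep_result <- function(x, ...) x$archive

#' One-row summary of a goal-exploration run
#' @param x a [run_gep()] result.
#' @param ... unused.
#' @return Final archive size, behavior-domain area and density,
#'   triphasic count/fraction and total runs.
#' @export
glance.gep_result <- function(x, ...) {
  gm <- grid_metrics(x$archive, x$grid)
  tibble::tibble(
    n_valid = nrow(x$archive),
    runs = if (nrow(x$history)) max(x$history$runs) else 0L,
    area = gm$area,
    density = gm$density,
    n_triphasic = sum(x$archive$triphasic),
    triphasic_fraction = mean(x$archive$triphasic)
  )
}
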