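#' Plot a recorded trial
#'
#' Stacked panels: elbow angle, the two muscle EMG envelopes, the two
#' alpha-motoneuron potentials, and the four proprioceptive afferents.
#'
#' @param object a `spinal_trace` from [run_trial()] or [synth_trace()].
#' @param channels optional character vector restricting the
#'   potential channels shown.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spinal_trace <- function(object,
                                  channels = c("flex_emg", "ext_emg",
                                               "FlxAlpha", "ExtAlpha",
                                               AFFERENT_NAMES),
                                  ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "time", "angle", dplyr::all_of(channels)),
    -"time", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("angle", channels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = "angle (deg) / membrane potential (mV)") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot the behavior domain of an exploration run
#'
#' Valid movements in (amplitude, maximal speed) space, triphasic ones
#' highlighted, over the occupancy grid.
#'
#' @param object a [run_gep()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gep_result <- function(object, ...) {
  arch <- object$archive
  g <- object$grid
  cells <- grid_metrics(arch, g)$cells
  ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = cells,
      ggplot2::aes(x = (.data$cx + 0.5) * g$cell_amplitude,
                   y = (.data$cy + 0.5) * g$cell_speed),
      width = g$cell_amplitude, height = g$cell_speed,
      fill = "grey92", colour = "grey80") +
    ggplot2::geom_point(
      data = arch,
      ggplot2::aes(x = .data$amplitude, y = .data$max_speed,
                   colour = .data$triphasic), size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "firebrick",
                                            `TRUE` = "goldenrod2")) +
    ggplot2::labs(x = "movement amplitude (deg)",
                  y = "maximal speed (deg/s)", colour = "triphasic") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Behavior-domain growth curves
#'
#' Area (occupied cells) and mean density of valid movements as a
#' function of the cumulated number of simulation runs.
#'
#' @param result a [run_gep()] result.
#' @return A ggplot object.
#' @export
plot_domain_growth <- function(result) {
  h <- tidyr::pivot_longer(result$history, c("area", "density"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$runs, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "simulation runs", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
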