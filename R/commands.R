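#' Command decoding ranges
#'
#' Physical ranges into which normalized `[0, 1]` command values are
#' mapped.  SET and GO currents span `[-current_max, current_max]` in
#' leak-conductance * mV units (so with the unit leak a full-scale command
#' shifts a neuron's steady potential by about +/- `current_max` mV,
#' negative values hyperpolarize); synapse gains span `[0, 1]` as
#' multipliers of each synapse's maximal conductance.
#'
#' @param current_max half-range of SET/GO currents.
#' @export
command_ranges <- function(current_max = 30) {
  stopifnot(current_max > 0)
  structure(list(current_max = current_max), class = "command_ranges")
}

#' Validate a normalized command vector
#'
#' @param values numeric vector in `[0, 1]`, ordered as SET-neuron
#'   currents, then SET-synapse gains, then GO currents.
#' @param topology a [build_topology()] object it must match in length.
#' @return The vector, invisibly classed `command_vector`.
#' @export
command_vector <- function(values, topology) {
  if (length(values) != topology$n_params) {
    stop(sprintf("command vector has length %d but topology '%s' needs %d",
                 length(values), topology$variant, topology$n_params),
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("command vector values must lie in [0, 1]", call. = FALSE)
  }
  structure(as.numeric(values), class = "command_vector")
}

#' Baseline command vector
#'
#' The encoding that decodes to zero currents and zero synapse gains
#' (range midpoint for currents, 0 for gains); it provably produces no
#' movement and no muscle force.
#'
#' @param topology a [build_topology()] object.
#' @export
baseline_vector <- function(topology) {
  n_set <- length(topology$set_neuron_targets)
  n_syn <- nrow(topology$synapses)
  n_go <- length(topology$go_targets)
  command_vector(c(rep(0.5, n_set), rep(0, n_syn), rep(0.5, n_go)), topology)
}

#' Decode a command vector into a SET/GO schedule
#'
#' Affine map of each normalized value into its physical range.  SET
#' currents (possibly hyperpolarizing) switch on at `set_time` = 1 s
#' together with the synapse gain multipliers; GO currents switch on at
#' `go_time` = 5 s; all are then held constant to the end of the trial
#' (10 s).  By default GO currents target the 8 interneurons only;
#' `go_include_alpha` additionally routes the first two GO values to the
#' alpha motoneurons (an alternative reading of the command targeting in
#' which GO directly releases the MNs).
#'
#' @param vector a [command_vector()] (or bare numeric in `[0, 1]`).
#' @param topology a [build_topology()] object.
#' @param ranges a [command_ranges()] object.
#' @param go_include_alpha also apply each side's PN GO current to its
#'   alpha MN (default `FALSE`).
#' @return A `command_schedule` list with named numeric vectors
#'   `set_current` (per SET-target neuron), `gain` (per synapse),
#'   `go_current` (per GO-target neuron) and the switch times.
#' @export
decode <- function(vector, topology, ranges = command_ranges(),
                   go_include_alpha = FALSE) {
  vector <- command_vector(vector, topology)
  n_set <- length(topology$set_neuron_targets)
  n_syn <- nrow(topology$synapses)
  n_go <- length(topology$go_targets)
  cm <- ranges$current_max
  set_current <- setNames((vector[seq_len(n_set)] - 0.5) * 2 * cm,
                          topology$set_neuron_targets)
  gain <- setNames(vector[n_set + seq_len(n_syn)],
                   paste(topology$synapses$pre, topology$synapses$post,
                         sep = "->"))
  go_current <- setNames((vector[n_set + n_syn + seq_len(n_go)] - 0.5) * 2 * cm,
                         topology$go_targets)
  if (go_include_alpha) {
    extra <- c(FlxAlpha = unname(go_current["FlxPN"]),
               ExtAlpha = unname(go_current["ExtPN"]))
    go_current <- c(go_current, extra[!is.na(extra)])
  }
  structure(
    list(set_time = 1, go_time = 5, end_time = 10,
         set_current = set_current, gain = gain, go_current = go_current),
    class = "command_schedule"
  )
}

#' Active command offsets at a time point
#'
#' @param schedule a [decode()]d `command_schedule`.
#' @param t time in seconds, within `[0, end_time]`.
#' @return A list with `set_current`, `gain`, `go_current`; components not
#'   yet switched on are zero.
#' @export
command_at <- function(schedule, t) {
  stopifnot(t >= 0, t <= schedule$end_time)
  set_on <- t >= schedule$set_time
  go_on <- t >= schedule$go_time
  list(
    set_current = if (set_on) schedule$set_current else
      setNames(rep(0, length(schedule$set_current)),
               names(schedule$set_current)),
    gain = if (set_on) schedule$gain else
      setNames(rep(0, length(schedule$gain)), names(schedule$gain)),
    go_current = if (go_on) schedule$go_current else
      setNames(rep(0, length(schedule$go_current)),
               names(schedule$go_current))
  )
}
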