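# Canonical node ordering shared by all circuit variants and by the
# simulation engine.  The first 12 are dynamic (leaky-integrator) neurons;
# the last 4 are afferent nodes whose potentials are set algebraically by
# the spindle/GTO models.
NEURON_NAMES <- c(
  "FlxAlpha", "ExtAlpha", "FlxGamma", "ExtGamma",
  "FlxPN", "ExtPN", "FlxIaIN", "ExtIaIN",
  "FlxIbIN", "ExtIbIN", "FlxRenshaw", "ExtRenshaw"
)
AFFERENT_NAMES <- c("Flx1a", "Ext1a", "Flx1b", "Ext1b")
ALL_NODE_NAMES <- c(NEURON_NAMES, AFFERENT_NAMES)

#' Non-spiking neuron specification
#'
#' @param name node label.
#' @param rest_potential mV.
#' @param membrane_time_constant seconds.
#' @param leak_conductance arbitrary conductance units (the network's
#'   conductance scale; synapse `max_conductance` is expressed in the same
#'   units).
#' @export
neuron_spec <- function(name, rest_potential = -60,
                        membrane_time_constant = 0.01,
                        leak_conductance = 1) {
  stopifnot(membrane_time_constant > 0, leak_conductance > 0)
  structure(
    list(name = name, rest_potential = rest_potential,
         membrane_time_constant = membrane_time_constant,
         leak_conductance = leak_conductance),
    class = "neuron_spec"
  )
}

#' Graded synaptic conductance
#'
#' Postsynaptic conductance rises linearly from 0 at the presynaptic
#' threshold potential to the maximal conductance at the presynaptic
#' saturation potential (and stays there above it).
#'
#' @param v_pre presynaptic membrane potential (mV).
#' @param syn one row of a topology's synapse table (or any list with
#'   `max_conductance`, `pre_threshold`, `pre_saturation`).
#' @param gain_multiplier dimensionless gain in `[0, Inf)`, normally the
#'   decoded SET synapse gain in `[0, 1]`.
#' @return Conductance (same units as `max_conductance`).
#' @export
graded_conductance <- function(v_pre, syn, gain_multiplier = 1) {
  stopifnot(all(gain_multiplier >= 0))
  frac <- (v_pre - syn$pre_threshold) /
    (syn$pre_saturation - syn$pre_threshold)
  gain_multiplier * syn$max_conductance * pmin(pmax(frac, 0), 1)
}

#' Advance a non-spiking neuron one time step
#'
#' Leaky-integrator dynamics
#' `C dV/dt = g_leak (rest - V) + sum_i g_i (E_i - V) + I`, with
#' `C = tau * g_leak`, integrated with one RK4 step under
#' piecewise-constant inputs.
#'
#' @param v membrane potential (mV).
#' @param synaptic_inputs list of `c(conductance, reversal)` pairs (or a
#'   two-column matrix), held constant over the step.
#' @param injected_current current in conductance-units * mV.
#' @param spec a [neuron_spec()].
#' @param dt time step (s).
#' @return Updated membrane potential (mV).
#' @export
neuron_step <- function(v, synaptic_inputs = list(), injected_current = 0,
                        spec, dt) {
  stopifnot(dt > 0)
  if (!is.finite(v)) stop("non-finite membrane potential", call. = FALSE)
  if (is.matrix(synaptic_inputs)) {
    g <- synaptic_inputs[, 1]; e <- synaptic_inputs[, 2]
  } else {
    g <- vapply(synaptic_inputs, `[`, numeric(1), 1)
    e <- vapply(synaptic_inputs, `[`, numeric(1), 2)
  }
  gl <- spec$leak_conductance
  cm <- spec$membrane_time_constant * gl
  f <- function(vv) {
    (gl * (spec$rest_potential - vv) + sum(g * (e - vv)) +
       injected_current) / cm
  }
  k1 <- f(v); k2 <- f(v + dt / 2 * k1); k3 <- f(v + dt / 2 * k2)
  k4 <- f(v + dt * k3)
  v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# One synapse-table row.
syn_row <- function(pre, post, sign) {
  tibble::tibble(pre = pre, post = post, sign = sign)
}

# Full 30-synapse wiring of the complete model, reconstructed from the
# described pathways.  Grouping: 12 Ia-related, 10 Ib-related, 8 core.
# Edges whose presence had to be inferred (not individually described) are
# the symmetric counterparts of described ones: FlxIbIN->ExtAlpha,
# FlxIbIN->ExtIbIN, FlxPN->ExtPN.
full_synapse_table <- function() {
  dplyr::bind_rows(
    # --- Ia pathways -----------------------------------------------------
    syn_row("Flx1a", "FlxAlpha", "exc"),   # monosynaptic stretch reflex
    syn_row("Flx1a", "FlxPN", "exc"),
    syn_row("Flx1a", "FlxIaIN", "exc"),
    syn_row("Ext1a", "ExtAlpha", "exc"),
    syn_row("Ext1a", "ExtPN", "exc"),
    syn_row("Ext1a", "ExtIaIN", "exc"),
    syn_row("FlxIaIN", "ExtAlpha", "inh"), # reciprocal inhibition
    syn_row("ExtIaIN", "FlxAlpha", "inh"),
    syn_row("FlxIaIN", "ExtIaIN", "inh"),  # mutual IaIN inhibition
    syn_row("ExtIaIN", "FlxIaIN", "inh"),
    syn_row("FlxRenshaw", "FlxIaIN", "inh"),
    syn_row("ExtRenshaw", "ExtIaIN", "inh"),
    # --- Ib pathways -----------------------------------------------------
    syn_row("Flx1b", "FlxIbIN", "exc"),
    syn_row("Flx1b", "FlxPN", "exc"),      # force-positive feedback via PN
    syn_row("Ext1b", "ExtIbIN", "exc"),
    syn_row("Ext1b", "ExtPN", "exc"),
    syn_row("FlxIbIN", "FlxAlpha", "inh"), # autogenic inhibition
    syn_row("ExtIbIN", "ExtAlpha", "inh"),
    syn_row("ExtIbIN", "FlxAlpha", "inh"), # crossed IbIN pathways
    syn_row("FlxIbIN", "ExtAlpha", "inh"),
    syn_row("ExtIbIN", "FlxIbIN", "inh"),
    syn_row("FlxIbIN", "ExtIbIN", "inh"),
    # --- core ------------------------------------------------------------
    syn_row("FlxPN", "FlxAlpha", "exc"),
    syn_row("ExtPN", "ExtAlpha", "exc"),
    syn_row("ExtPN", "FlxPN", "inh"),      # crossed PN inhibition
    syn_row("FlxPN", "ExtPN", "inh"),
    syn_row("FlxAlpha", "FlxRenshaw", "exc"),
    syn_row("ExtAlpha", "ExtRenshaw", "exc"),
    syn_row("FlxRenshaw", "FlxAlpha", "inh"),
    syn_row("ExtRenshaw", "ExtAlpha", "inh")
  )
}

IA_NODES <- c("Flx1a", "Ext1a")
IB_NODES <- c("Flx1b", "Ext1b")
IAIN <- c("FlxIaIN", "ExtIaIN")
IBIN <- c("FlxIbIN", "ExtIbIN")
PNS <- c("FlxPN", "ExtPN")
RENSHAW <- c("FlxRenshaw", "ExtRenshaw")
ALPHAS <- c("FlxAlpha", "ExtAlpha")
GAMMAS <- c("FlxGamma", "ExtGamma")

drop_synapses_touching <- function(syn, nodes) {
  syn[!(syn$pre %in% nodes | syn$post %in% nodes), ]
}

#' Build a named circuit variant
#'
#' Returns the wiring and SET/GO parameter-target lists of one of the five
#' circuit variants.  The total parameter count (SET neuron currents +
#' SET synapse gains + GO interneuron currents) equals the number in the
#' variant's name:
#'
#' * `full50` - complete network: 12 SET neurons, 30 synapses, 8 GO INs.
#' * `noIb36` - Ib afferents, Ib INs and their synapses removed.
#' * `iaOnly14` - only monosynaptic Ia and Ia->PN->MN pathways, no
#'   crossed connections, no Ia/Ib/Renshaw INs.
#' * `noIa34` - Ia afferents, Ia INs and their synapses removed (gamma
#'   motoneurons remain as inert SET targets).
#' * `noFeedback38` - all proprioceptive afferents and the gamma
#'   motoneurons removed, all interneurons and central connections kept.
#'
#' Synapse parameters default to threshold -60 mV, saturation -20 mV,
#' excitatory reversal -10 mV, inhibitory reversal -80 mV and a maximal
#' conductance of 3 leak units; all are columns of the returned synapse
#' table and may be edited before simulation.
#'
#' @param variant one of `"full50"`, `"noIb36"`, `"iaOnly14"`, `"noIa34"`,
#'   `"noFeedback38"`.
#' @param gmax maximal synaptic conductance (leak-conductance units).
#' @param e_exc,e_inh excitatory/inhibitory reversal potentials (mV).
#' @param pre_threshold,pre_saturation graded-transmission limits (mV).
#' @return A `circuit_topology` list: `variant`, `neurons` (tibble),
#'   `synapses` (tibble), `set_neuron_targets`, `set_synapse_targets`
#'   (synapse indices), `go_targets`, `n_params`.
#' @export
build_topology <- function(variant = c("full50", "noIb36", "iaOnly14",
                                       "noIa34", "noFeedback38"),
                           gmax = 3, e_exc = -10, e_inh = -80,
                           pre_threshold = -60, pre_saturation = -20) {
  variant <- match.arg(variant)
  syn <- full_synapse_table()
  set_neurons <- NEURON_NAMES
  go <- c(PNS, IAIN, IBIN, RENSHAW)
  afferents <- c(IA_NODES, IB_NODES)

  if (variant == "noIb36") {
    syn <- drop_synapses_touching(syn, c(IB_NODES, IBIN))
    set_neurons <- setdiff(set_neurons, IBIN)
    go <- setdiff(go, IBIN)
    afferents <- IA_NODES
  } else if (variant == "iaOnly14") {
    keep <- with(syn, (pre %in% c("Flx1a") & post %in% c("FlxAlpha", "FlxPN")) |
                   (pre %in% c("Ext1a") & post %in% c("ExtAlpha", "ExtPN")) |
                   (pre == "FlxPN" & post == "FlxAlpha") |
                   (pre == "ExtPN" & post == "ExtAlpha"))
    syn <- syn[keep, ]
    set_neurons <- c(ALPHAS, GAMMAS, PNS)
    go <- PNS
    afferents <- IA_NODES
  } else if (variant == "noIa34") {
    syn <- drop_synapses_touching(syn, c(IA_NODES, IAIN))
    set_neurons <- setdiff(set_neurons, IAIN)
    go <- setdiff(go, IAIN)
    afferents <- IB_NODES
  } else if (variant == "noFeedback38") {
    syn <- drop_synapses_touching(syn, c(IA_NODES, IB_NODES))
    set_neurons <- setdiff(set_neurons, GAMMAS)
    afferents <- character(0)
  }

  rest <- ifelse(ALL_NODE_NAMES %in% AFFERENT_NAMES, -65, -60)
  neurons <- tibble::tibble(
    name = ALL_NODE_NAMES,
    kind = ifelse(ALL_NODE_NAMES %in% AFFERENT_NAMES, "afferent", "neuron"),
    rest_potential = rest,
    membrane_time_constant = 0.01,
    leak_conductance = 1,
    active = ALL_NODE_NAMES %in% c(set_neurons, afferents) |
      ALL_NODE_NAMES %in% NEURON_NAMES & ALL_NODE_NAMES %in%
        unique(c(syn$pre, syn$post))
  )

  syn$max_conductance <- gmax
  syn$pre_threshold <- pre_threshold
  syn$pre_saturation <- pre_saturation
  syn$reversal <- ifelse(syn$sign == "exc", e_exc, e_inh)

  topo <- structure(
    list(
      variant = variant,
      neurons = neurons,
      synapses = tibble::as_tibble(syn),
      afferent_nodes = afferents,
      set_neuron_targets = set_neurons,
      set_synapse_targets = seq_len(nrow(syn)),
      go_targets = go,
      n_params = length(set_neurons) + nrow(syn) + length(go)
    ),
    class = "circuit_topology"
  )
  expected <- c(full50 = 50, noIb36 = 36, iaOnly14 = 14, noIa34 = 34,
                noFeedback38 = 38)
  stopifnot(topo$n_params == expected[[variant]])
  topo
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(sprintf(
    "<circuit_topology '%s'>: %d parameters (%d SET neurons + %d synapses + %d GO INs)\n",
    x$variant, x$n_params, length(x$set_neuron_targets),
    nrow(x$synapses), length(x$go_targets)
  ))
  invisible(x)
}
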