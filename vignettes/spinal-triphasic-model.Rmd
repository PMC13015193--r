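---
title: "A closed-loop spinal sensorimotor model of triphasic muscle commands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop spinal sensorimotor model of triphasic muscle commands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(triphasim)
```

## The question the model addresses

During fast single-joint movements, the EMGs of the antagonistic muscle
pair show a stereotyped *triphasic* sequence: a first agonist burst
(AG1) that launches the limb, an antagonist burst (ANT) that brakes it,
and a second agonist burst (AG2) that damps the terminal oscillation.
Whether this temporal patterning must be composed by the brain, or can
be generated by spinal sensorimotor circuits interacting with the limb,
is a long-standing debate. `triphasim` implements a model built to probe
the spinal hypothesis under the most restrictive condition possible: the
descending commands are *constant step functions* — a SET step at 1 s
that configures the network and a GO step at 5 s that releases the
movement, both held to the end of the 10 s trial.  Since steps carry no
temporal information, any burst structure in the muscle commands must
emerge from the loop between the spinal network, the proprioceptors and
the musculoskeletal plant.

## The plant

A forearm+hand segment rotates about the elbow (0° = full extension,
hard stops at 0° and 120°, no gravity) under two antagonistic linear
Hill muscles (biceps/triceps).  Each muscle integrates

$$\frac{dT}{dt} = \frac{K_{se}}{B}\Big(K_{pe}\,\Delta x + B\,\dot{x}
  - \big(1 + K_{pe}/K_{se}\big)\,T + A\Big),$$

with serial stiffness $K_{se}$ = 1000 N/m, parallel stiffness $K_{pe}$ =
100 N/m and damping $B$ = 1 N·s/m.  The active drive $A$ is the product
of a stimulus–tension sigmoid of the muscle membrane potential
(amplitude 400/300 N, midpoint −20/−30 mV, vertical offset −4.5/−4 N for
biceps/triceps) and an inverted-parabola length–tension bell (center
38.5 cm, half-width 14/35 cm), capped at the muscle's maximal tension
(400/300 N).  Muscle path length is an affine function of elbow angle
(biceps 34 → 25 cm and triceps 27.5 → 34.5 cm across 0–120°), so moment
arms are constant (4.30 and 3.34 cm).

Design choices a reader should know about:

* **Stimulus–tension steepness.** The published steepness of 100 makes
  the sigmoid a numerical step on a millivolt axis, so the working
  steepness is `100 / st_scale` per mV with `st_scale = 250`.  Force
  onset then sits near −31 mV of muscle membrane potential: there is a
  subthreshold band (−60 to about −31 mV) in which the muscle membrane
  is visibly depolarized but develops no force.  This band turned out to
  be functionally important: it gives exploration a margin in which
  residual motoneuron activity after the movement is harmless, which is
  what makes the valid-movement manifold wide enough for random goal
  exploration to traverse.  Configurations with force onset close to
  rest (−58 mV) were tried and produced archives that could not expand
  beyond slow, small movements.
* **Passive slack length.** The parallel elastic element's slack length
  defaults to the muscle's longest in-range path length, so a resting
  muscle produces no force anywhere in the joint's working range and the
  zero-activation plant is stationary at every angle.  The anatomical
  muscle length from the parameter table is kept as a recorded field.
* **Joint damping.** The model needs a viscous term at the joint for a
  well-conditioned search landscape.  With 0.05 N·m·s/rad the arm coasts
  for seconds and every clean stop must be fully active; seeding then
  converges to degenerate slow drifts.  At 0.25 N·m·s/rad exploration is
  easy but terminal oscillations are passively damped, so the second
  agonist burst loses its function and triphasic patterns all but
  disappear.  The default is 0.15 N·m·s/rad, the middle ground at which
  exploration remains feasible while fast stops still benefit from
  active braking — the regime in which triphasic commands emerge.
* **Inertia.** The forearm is a uniform rod ($mL^2/3$) plus the hand as
  a point mass at forearm length + half hand length, from the published
  segment masses/lengths: 0.161 kg·m².
* **Integration.** Fixed-step RK4 at 1 ms (compiled core, with a pure-R
  twin used in tests), recording decimated to 10 ms — the sampling at
  which the cost is defined.  All conductance loads stay well inside the
  explicit-integration stability limit.

## The spinal network

Twelve non-spiking (rate-like) neurons — 2 alpha motoneurons, 2 gamma
motoneurons, 2 propriospinal interneurons (PN), 2 Ia interneurons, 2 Ib
interneurons, 2 Renshaw cells — plus four afferent nodes (Flx1a, Ext1a,
Flx1b, Ext1b).  Neurons are leaky integrators
($C\dot V = g_{leak}(V_{rest}-V) + \sum g_i(E_i-V) + I$, $\tau$ = 10 ms,
rest −60 mV) and synapses are graded: postsynaptic conductance rises
linearly from 0 at a presynaptic threshold (−60 mV) to the maximal
conductance (3 leak units) at saturation (−20 mV); reversal potentials
are −10 mV (excitatory) and −80 mV (inhibitory; glycinergic reversals
sit well below rest, and inhibition weaker than this cannot gate the
tonically active stretch afferent drive).  These values are not
published for the original network and are configurable columns of the
wiring table.

The complete model's 30 synapses are reconstructed from the pathways the
source describes: monosynaptic Ia excitation of the homonymous MN and
PN, Ia→IaIN with reciprocal and mutual IaIN inhibition and Renshaw→IaIN;
Ib→IbIN and Ib→PN force feedback with autogenic and crossed IbIN
inhibition; PN→MN excitation with crossed PN inhibition; and the Renshaw
loop.  The five variants expose 50, 36, 14, 34 and 38 command
parameters; the counts decompose as SET-neuron targets + synapse gains +
GO-interneuron targets and are asserted in the test suite.  Two
reconstruction choices could not be settled from the text: the
34-parameter (no-Ia) variant keeps the gamma motoneurons as (inert) SET
targets while the 38-parameter (no-feedback) variant drops them — the
only decomposition consistent with both printed counts — and the crossed
PN connection is taken as inhibitory.

A command vector is normalized to $[0,1]^n$: SET neuron currents map
affinely to ±30 current units (midpoint = 0, negative values
hyperpolarize), synapse gains map to $[0,1]$ multipliers of the maximal
conductance, GO interneuron currents map to ±30.  GO targets the eight
interneurons by default; a switch (`go_include_alpha`) additionally
routes each side's PN GO current to its alpha MN, since the source
describes GO both ways in different places.  The default follows the
explicit "8 INs" statement.

## Afferents

The muscle spindle is a miniature Hill element sharing the muscle's
attachments.  Its slack length is the muscle's shortest in-range length,
so spindle tension encodes muscle length, and its serial-tension rate
carries velocity/acceleration sensitivity.  The Ia potential is
$-65 + k_T T + k_{dT} \dot T$ mV ($k_T$ = 15 mV/N, $k_{dT}$ = 3.5 mV·s/N),
clamped to rest while the spindle is slack — which reproduces the
classic fingerprints: silence during an unloaded release, rescue of the
release response by fusimotor (gamma) drive, and an onset transient
exceeding the tonic plateau for ramps faster than about 1 s.  A single
mixed-type gamma motoneuron per muscle scales the spindle's active drive
(0.2 N per suprathreshold mV).  These gains were hand-tuned against the
qualitative features above; only those features, not the numbers, are
testable.

The Golgi tendon organ is a memoryless saturating affine map of muscle
tension, $-65 + 0.3\,T$ mV capped at −10 mV.  No equations for the GTO
are published; linearity-with-saturation is the simplest form with the
right monotonicity.

## Scoring movements

For each trial the elbow-angle trace is fitted with a minimum-jerk
template $\theta(t) = A\,(10\tau^3 - 15\tau^4 + 6\tau^5)$: the amplitude
is the terminal plateau minus the pre-GO angle, and onset/duration are
found by a coarse grid refined with box-constrained optimization,
minimizing the mean squared error over $t \in [2,10]$ s at 10 ms
sampling (desired angle flat before onset).  The cost adds two
co-contraction penalties — the time-averaged product of the
suprathreshold parts of the two MN potentials over the preparatory
([2, 5] s) and maintained ([7, 10] s) windows, scaled by 100.  The
literal product form would reward two silenced MNs
(negative × negative > 0), so each factor is clamped at zero below the
−60 mV threshold.  The tracking sum is implemented as a mean (the same
quantity is called an MSE where the validity threshold of 1 is
introduced, and only a mean makes that threshold meaningful in
degrees²).  A movement is **valid** when cost < 1, amplitude ∈ [10°,
110°], movement duration ≤ 2 s and the movement is a flexion.  Duration
is measured as the time from 5% to 95% of amplitude along the fitted
template (≈ 0.607 of the template duration); the source never defines
its measure.

EMG is the muscle membrane potential itself (graded transmission, no
spikes).  Peaks are all local maxima above the −60 mV baseline —
including the smallest — with plateaus reporting their center sample;
minima are located between consecutive maxima.  Peak analysis reads the
trace from t = 2 s on, after the SET transients have settled, so the
brief step-onset transient at 1 s is not mistaken for a movement burst.
A movement is **triphasic** when the flexor shows at least two peaks
and an extensor peak falls strictly between the first two flexor peaks;
a silent period between AG1 and AG2 is reported but not required.  The
same rule applied to the alpha-MN potentials defines MN-level triphasism;
because the muscle is driven by its MN through a thresholded synapse,
EMG-level triphasism implies MN-level triphasism but not conversely.

## Seeding and goal exploration

Exploration needs initial valid movements.  They are found with a
bounded CMA-ES (rank-one + rank-mu covariance update, cumulative
step-size adaptation, population $4 + \lfloor 3\ln n\rfloor$),
minimizing the tracking-plus-penalty cost toward a relaxed target
template (30°, 1 s), with every valid movement encountered along the way
harvested as a seed.  The initial step size is 0.005 on the normalized
scale with exploration limits covering the full $[0,1]$ range;
candidates are repaired onto the bounds before simulation.  Two
robustness devices were added after observing the search stall on the
no-movement plateau (where small steps change nothing and the step size
collapses): the initial mean is the best of a 300-trial random probe,
and successive restarts raise the initial step size tenfold (capped at
0.3).  The first restart honors the published 0.005.

The random goal exploration process (rGEP) then iterates: sample a goal
in (amplitude, max-speed) space — on the periphery of the known domain
(*extend*: a uniform point in an empty cell of the one-cell dilation
ring around the occupied region) or inside a hole (*fill*: an empty cell
with occupied cells on at least two of its four orthogonal sides,
falling back to extend when no hole exists) — retrieve the archived
movement nearest to the goal (Euclidean distance with amplitude scaled
by 110° and speed by 300 °/s, ties to the lowest id), replay its
parameters with independent Gaussian noise (sd 0.02 per coordinate,
clipped to $[0,1]$), and store the result if and only if it is valid.
Goals per round scale with the boundary length (floor 4, cap 25), which
is why runs per round grow as the domain grows.  The behavior-domain
area is the number of 5° × 10 °/s grid cells holding at least one valid
movement; density is valid movements per occupied cell.  Cell sizes are
not published; these defaults put the observed domain at a few dozen
cells in scaled-down runs.

## What the scaled-down runs show — and what they cannot

At the problem sizes used in the tests and the acceptance script
(seeding budgets of a few thousand trials, 60–150 extend rounds — a few
thousand rGEP runs, versus hundreds of thousands in a full-scale study),
the complete 50-parameter circuit yields archives of several hundred
valid movements, spanning from the 10° validity floor up to flexions of
50–110° with peak speeds approaching 200 °/s, in which a substantial
subset of movements carries a genuine EMG triphasic pattern, and
triphasic movements sit at significantly higher speeds than
non-triphasic ones (one-sided rank test).  Replaying a discovered
triphasic movement with the flexor spindle afferent clamped at −65 mV
abolishes the movement, and suppressing the Ext1b→ExtPN synapse on such
a movement abolishes the second flexor-MN peak — the two key
circuit-dissection results.  The variant lacking Ib feedback still
produces valid (slower) movements but no EMG triphasic pattern.
Headline full-scale numbers (exact domain extents, a 30.3% triphasic
fraction, specific correlation coefficients) depend on unpublished
parameter sets and six-figure run counts and are not reproduced as exact
values; only their qualitative structure is.

The synthetic-trace generator (`synth_trace()`) emulates exactly what
the evaluation stack consumes — a minimum-jerk angle trajectory with
optional white angle noise and Gaussian activity bumps on any membrane
channel.  It does not emulate closed-loop dynamics, reflex latencies or
co-articulated channel correlations, so tests built on it validate the
*scoring* machinery, not the simulator; simulator-level claims are
always tested on simulated traces.

## Numerical and degenerate-input conventions

Tension states are clamped non-negative (with the derivative zeroed when
a slack element would be pulled further negative); the angle is clipped
at the stops with the into-stop velocity zeroed; a numerically unstable
trial is returned truncated and flagged, and scored as an invalid
movement with reason `"unstable"` rather than raising an error, so
exploration loops continue.  Lesion clamps override node outputs at
every substep; suppressing a synapse absent from a variant warns and is
a no-op.  All trials are bit-deterministic given their inputs; the only
randomness in the package lives in the explicit RNG draws of the probe,
CMA-ES, goal sampling and perturbation, all driven by the caller's seed.

## Known limitations

* The 30-synapse wiring and all membrane/synapse constants are
  reconstructions; different reconstructions reproduce the same
  qualitative phenomena with different behavior-domain shapes.
* The subthreshold muscle band means the muscle membrane potential can
  sit above −60 mV without force; solutions exploiting this band have
  EMG envelopes that do not return exactly to baseline, which is why
  peak analysis is windowed to the post-SET phase.
* Movement validity is enforced through the scalar cost; there is no
  separate oscillation statistic beyond the MSE gate.
* A single mixed gamma motoneuron per muscle; separate static/dynamic
  fusimotor control, gravity, and multi-joint plants are out of scope.
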