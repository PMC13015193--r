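# triphasim

During a fast elbow flexion, the EMGs of the antagonistic muscle pair
show a stereotyped **triphasic pattern**: a first agonist burst (AG1)
that accelerates the limb, an antagonist burst (ANT) that brakes it, and
a second agonist burst (AG2) that damps the terminal oscillation. Is
this temporal patterning composed in the brain, or can spinal
sensorimotor circuits generate it on their own? `triphasim` is an R
package for probing the spinal hypothesis by simulation, for
computational neuroscientists and motor-control researchers.

The model is deliberately restrictive about what the brain contributes:
descending drive consists only of **constant step commands** — a SET
step at t = 1 s that configures the spinal network (neuron bias
currents and synapse gains) and a GO step at t = 5 s that triggers the
movement, both held to the end of the 10 s trial. Steps carry no
temporal information, so any burst structure in the muscle commands must
emerge from the closed loop between:

* a single-joint elbow plant (no gravity, hard stops at 0° and 120°)
  driven by two antagonistic linear Hill muscles,
  `dT/dt = (Kse/B) (Kpe Δx + B dx/dt − (1 + Kpe/Kse) T + A)`, with the
  active drive `A` the product of a stimulus–tension sigmoid of the
  muscle membrane potential and a length–tension bell;
* a non-spiking spinal network (2 alpha MNs, 2 gamma MNs, 2
  propriospinal INs, 2 Ia INs, 2 Ib INs, 2 Renshaw cells) with graded
  synapses, in five variants exposing 50/36/14/34/38 command
  parameters;
* muscle-spindle Ia afferents (miniature Hill elements with fusimotor
  gamma drive; output `rest + k_T T + k_dT dT/dt`) and Golgi tendon
  organ Ib afferents (saturating affine in muscle tension).

Movements are scored against the minimum-jerk template
`θ(t) = A (10τ³ − 15τ⁴ + 6τ⁵)`: the cost is the mean squared tracking
error over t ∈ [2, 10] s plus co-contraction penalties
`100 · mean(max(0, V_flex + 60) · max(0, V_ext + 60))` over the
preparatory ([2, 5] s) and maintained ([7, 10] s) windows; a movement is
*valid* when cost < 1, amplitude ∈ [10°, 110°], duration ≤ 2 s, flexion
direction. Valid command vectors are discovered by a bounded CMA-ES
seeder and a **random goal exploration process** (rGEP): sample a goal
on the periphery of (extend) or inside (fill) the known behavior domain
in (amplitude, peak speed) space, replay the nearest archived solution's
parameters with Gaussian noise, and keep the result iff valid. A
movement is *triphasic* when its flexor EMG envelope shows two peaks
with an extensor peak strictly between them.

## A worked example

The evaluation stack is independent of the simulator and can be
exercised on a synthetic trace — a minimum-jerk trajectory with Gaussian
activity bumps on the two EMG channels:

```r
library(triphasim)

topo <- build_topology("full50")
#> <circuit_topology 'full50'>: 50 parameters (12 SET neurons + 30 synapses + 8 GO INs)

# the baseline command vector provably does nothing
trace0 <- run_trial(baseline_vector(topo), topo)
range(trace0$angle)
#> [1] 0 0

# a synthetic 42.88-degree movement with an AG1-ANT-AG2 burst sequence
trace <- synth_trace(
  amplitude = 42.88, duration = 0.8,
  bumps = list(flex_emg = bump_set(c(5.15, 5.80), c(28, 12), 0.06),
               ext_emg  = bump_set(5.45, 20, 0.06)))
evaluate_movement(trace)
#>   amplitude max_speed duration mse cost valid triphasic ag1_time ant_time ag2_time
#>       42.88     100.5    0.497   0    0  TRUE      TRUE     5.15     5.45      5.8
```

The movement is valid (cost 0 < 1, amplitude inside [10°, 110°],
duration 0.497 s) and triphasic (extensor peak at 5.45 s strictly
between the flexor peaks at 5.15 and 5.80 s). `fit_minjerk()` recovers
the generating template exactly (amplitude 42.9°, duration 0.800 s, mse
≈ 6e-16), and `autoplot(trace)` draws the angle and membrane-potential
channels.

Discovering real movements runs the full loop (several minutes):

```r
set.seed(1)
seeds   <- seed_search(topo, seeder_config())        # CMA-ES harvesting
result  <- run_gep(seeds, trial_evaluator(topo),     # goal exploration
                   gep_config(n_extend_rounds = 120, n_fill_rounds = 20))
glance(result)        # archive size, behavior-domain area, triphasic fraction
autoplot(result)      # the behavior domain, triphasic movements highlighted
```

Mechanism analyses replay archived movements under lesions
(`lesion_screen()`: clamped afferents, suppressed synapses) and
correlate burst-peak amplitudes across the archive
(`movement_peak_amplitudes()`, `peak_correlations()`).

## The methods vignette

`vignettes/spinal-triphasic-model.Rmd` documents the model equations and
every design decision: plant constants, the reconstructed 30-synapse
wiring, afferent gains and what they were tuned against, cost
conventions and degenerate-input handling, the seeder and exploration
defaults, and what the scaled-down runs do and do not establish.
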