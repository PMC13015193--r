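Package: triphasim
Title: Closed-Loop Spinal Sensorimotor Circuit Simulation and Goal Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a single-joint elbow plant driven by two
    antagonistic linear Hill muscles, a rate-based (non-spiking) spinal
    sensorimotor network with graded synapses, and muscle spindle (Ia) and
    Golgi tendon organ (Ib) proprioceptive feedback. Descending drive is
    restricted to constant SET and GO step commands, so any temporal
    patterning of the muscle commands (in particular the triphasic
    agonist-antagonist-agonist burst sequence of fast movements) must emerge
    from the spinal circuit interacting with the musculoskeletal system.
    Includes minimum-jerk template fitting and movement scoring with
    co-contraction penalties, EMG peak extraction and triphasic
    classification, a bounded CMA-ES seeder, a random Goal Exploration
    Process (rGEP) that maps the reachable behavior domain in
    amplitude-speed space, and lesion-replay and peak-correlation analyses
    of the mechanisms behind the second agonist burst.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
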