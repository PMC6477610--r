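Package: snscpg
Title: Two-Layer Central Pattern Generator Networks of Non-Spiking Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates synthetic nervous systems built from non-spiking
    leaky-integrator neurons with persistent sodium currents and graded
    (piecewise-linear) synapses, organised as a two-layer locomotor central
    pattern generator: a half-center rhythm generator that keeps step-cycle
    time, pattern formation networks (including a shared knee-ankle synergy
    group) that distribute the rhythm, and a motoneuron/Renshaw output
    layer.  Provides network builders, fixed-step exponential-Euler and
    Runge-Kutta integrators, stimulus and noise protocols, rhythm analysis
    (threshold-crossing cycle detection, period tables, phase-shift and
    resetting/non-resetting classification of deletions), canned
    experiments for descending-drive and pattern-formation "memory" tests,
    and a deliberately minimal one-degree-of-freedom mechanical plant with
    linear afferent feedback for closed-loop demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
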