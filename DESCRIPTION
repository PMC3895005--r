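Package: ionpull
Title: Step-Wise Pulling, Jarzynski Free-Energy Profiles, and Ion-Channel
    Conductance Estimation
Version: 0.1.0
Authors@R:
    person("Ionpull", "Developers", email = "ionpull@example.org",
           role = c("aut", "cre"))
Description: Toolkit for analysing step-wise pulling simulations of an ion
    moving along a one-dimensional reaction coordinate under a stepped
    harmonic bias. Implements free-energy profile estimation from
    per-step work distributions via Jarzynski's equality and a stepwise
    quasi-equilibrium (free-energy-perturbation) estimator, stable-state
    identification from pooled position histograms with Gaussian-mixture
    decomposition, force-distribution transition probabilities,
    distribution-overlap detailed-balance diagnostics, and single-channel
    conductance estimation from work and displacement statistics. A
    built-in overdamped Langevin engine over configurable multi-well
    potentials provides a fully synthetic, seed-deterministic stand-in
    for molecular-dynamics trajectories, so every estimator is testable
    against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
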