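Package: oneopes
Title: OneOPES Replica-Ladder Enhanced Sampling and Funnel Binding Free Energies
Version: 0.1.0
Authors@R:
    person("OneOPES", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for the OneOPES multi-replica enhanced-sampling scheme:
    OPES Explore bias potentials, weak multi-CV auxiliary biases, an OPES
    MultiThermal expanded-temperature bias, Metropolis bias exchanges across
    an eight-replica ladder, and the funnel-restraint post-processing that
    turns replica-0 time series into absolute binding free energies with
    block-average errors. Ships analytic toy Langevin systems on which exact
    free energies are computable by quadrature, PLUMED-dialect COLVAR input
    and output, per-replica PLUMED protocol emission, and the benchmark
    metrics (Kendall tau, linear fit, MAE/ME/RMSE) with bootstrap confidence
    intervals used to score predicted against experimental affinities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
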