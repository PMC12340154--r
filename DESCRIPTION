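Package: fsdyn
Title: Stochastic Frontostriatal Circuit Models, Bayesian Fitting and Virtual Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for ventral and dorsal
    frontostriatal circuit dynamics at rest. Implements a reduced Wong-Wang
    neural mass model with mean-reverting (Ornstein-Uhlenbeck) striato-cortical
    couplings integrated by Euler-Maruyama, a Balloon-Windkessel hemodynamic
    forward model, deterministic stability and bifurcation analysis, functional
    connectivity and Wasserstein cohort distances, approximate Bayesian
    computation by sequential Monte Carlo for group-level fitting, a
    combinatorial virtual-intervention framework scored by Mann-Whitney AUC,
    digital-twin pairing of subjects to simulations, and a synthetic-data
    generator emulating two-group functional connectivity studies with
    longitudinal symptom scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
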