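Package: kprsim
Title: Stochastic Simulation and Information-Theoretic Analysis of Kinetic Proofreading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Event-driven stochastic simulation of kinetic proofreading (KPR)
    schemes with non-exponential (Erlang or deterministic) processing times,
    covering DNA-replication fidelity and T cell receptor ligand
    discrimination. Provides closed-form accuracy, speed and channel-capacity
    expressions for first-passage-time and product-counting discrimination
    strategies, empirical mutual-information and channel-capacity estimators,
    static and dynamic product-count thresholds, and a registry of
    reproducible parameter-sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
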