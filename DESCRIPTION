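Package: edtwin
Title: Discrete-Event Digital Twin of an Emergency Department
Version: 0.1.0
Authors@R: person("ED", "Modelling", email = "ed.modelling@example.org",
    role = c("aut", "cre"))
Description: A desk-scale digital twin of an emergency department (ED):
    a discrete-event simulation of patient flow through registration,
    triage, bed placement, physician consultation, testing, reassessment
    and discharge, driven by non-homogeneous Poisson arrivals and
    textbook service-time laws (triangular, gamma, lognormal,
    exponential). The package computes door-to-doctor and length-of-stay
    key performance indicators, validates them against reference
    statistics by a signed percentage difference, runs three-level
    full-factorial experiments over nurse and bed capacities with common
    random numbers, fits interaction regressions with partial-F ANOVA
    and standardized-effect (Pareto) rankings, and calibrates free model
    parameters by a box-constrained Nelder-Mead search. A synthetic
    event-log generator stands in for confidential hospital timestamp
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
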