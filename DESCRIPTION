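Package: miuflow
Title: Simulation-Based Multiobjective Optimization of Emergency
    Department Fast-Track Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of emergency department (ED) patient
    flow with a fast-track Minor Injuries Unit (MIU), and a neural-network
    metamodeling approach to the multiobjective problem of allocating MIU
    resources (daily opening and closing hours, rooms, triage diversion
    percentages). The simulator produces sample-average estimates of
    door-to-doctor time (DTDT) by severity tag and unit; a multilayer
    perceptron surrogate trained on simulated designs exposes values and
    input gradients of the expected waiting-time objective, so that the
    weighting method with a gradient-based solver generates Pareto-optimal
    trade-offs between patient waiting time and MIU operating hours. A
    derivative-free baseline optimizer and an end-to-end pipeline driver
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
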