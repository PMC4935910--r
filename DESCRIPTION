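Package: stochsis
Title: Thresholds, Simulation and Persistence Analysis for a Stochastic
    SIS Epidemic Model with Nonlinear Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a susceptible-infectious-susceptible (SIS) epidemic
    model whose transmission coefficient is perturbed by white noise and whose
    incidence rate is a general nonlinear function f(S,I) (bilinear, standard,
    saturated, Beddington-DeAngelis, product or user-supplied forms).
    Computes the basic reproduction number R0, the noise-modified threshold,
    the critical noise intensities separating extinction from persistence,
    and classifies the dynamical regime; simulates trajectories with a
    Milstein-type discretization; locates the deterministic endemic
    equilibrium and the stochastic oscillation level of the infectious
    class; and evaluates permanence-in-mean lower bounds and empirical
    stationary-distribution summaries from simulated ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
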