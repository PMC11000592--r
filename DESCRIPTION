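Package: nanodegosc
Title: Design of Genetic Oscillators via NanoDeg-Mediated Protein Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic simulation and bifurcation analysis of synthetic
    gene circuits whose oscillatory behaviour is created or tuned by
    post-translational depletion of network components with a NanoDeg (a
    nanobody-degron fusion that routes a bound target to proteasomal
    degradation). Implements reduced ODE/DDE models of five circuit
    topologies (activator-repressor, delayed Goodwin oscillator,
    repressilators with a common or with individual NanoDegs, and a
    mixed-mode repressilator in which the NanoDeg is itself a node),
    stiff-capable integration on a fixed 0.01 h reporting grid, extraction of
    oscillation amplitude and period from zero crossings of the zero-mean
    trajectory, classification of the long-run dynamic regime, parameter
    sweeps with bisection-refined oscillation windows and critical (Hopf)
    values, and an independent linear-stability oracle based on Jacobian
    eigenvalues and rightmost characteristic roots of the delay system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
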