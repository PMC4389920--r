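Package: plaquestab
Title: Stability Analysis of an Atherosclerotic Plaque Inflammation Model
Version: 0.1.0
Authors@R:
    person("Plaque", "Stability Maintainers", email = "maintainers@plaquestab.org",
           role = c("aut", "cre"))
Description: Tools for analysing a three-species reaction-diffusion-chemotaxis
    model of early atherosclerotic plaque inflammation (oxidised LDL,
    macrophages, necrotic lipids) in the arterial intima.  Computes the
    spatially homogeneous equilibrium and its linearisation, evaluates an ODE
    spectral stability criterion and two sufficient PDE stability criteria,
    constructs and verifies an explicit energy-estimate (Lyapunov) certificate
    with an exponential decay-rate bound, and validates the criteria
    numerically with a method-of-lines simulator on an eccentric annulus
    discretised in bipolar coordinates, including energy diagnostics and a
    stable/unstable trajectory classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
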