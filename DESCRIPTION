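Package: thermoembo
Title: Mass and Energy Transport Simulation for Thermoembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thermoembolization, the endovascular delivery of an
    exothermically hydrolyzing acid chloride (dichloroacetyl chloride, DCACl)
    dissolved in oil. Couples two-phase Darcy flow in porous tissue
    (blood displaced by the injected bolus, Brooks-Corey capillary pressure),
    first-order hydrolysis kinetics with inter-phase mass exchange, and a
    mixture-temperature convection-diffusion-reaction equation, discretized
    with a cell-centered finite-volume method and backward-Euler implicit time
    stepping with upwind stabilization. Includes synthetic vascular geometry
    generation, an injection-schedule model, thermometry-style validation
    analytics (line profiles, probe time series, noisy frame synthesis,
    profile comparison statistics), and nonlinear least-squares fitting of the
    hydrolysis rate constant from time-temperature curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    generics,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
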