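Package: cdtk
Title: Two-Phase Toxicokinetic Modelling of Dietary Cadmium in Ant Colonies
Version: 0.1.0
Authors@R: person("cdtk", "maintainers", email = "cdtk@example.org",
    role = c("aut", "cre"))
Description: Fits a two-phase one-compartment toxicokinetic model (uptake
    followed by depuration, continuous at the food switch) to colony-level
    internal cadmium concentrations by Gauss-Newton nonlinear least squares,
    compares pooled against habitat-indexed parameterisations with AIC and
    the extra-sum-of-squares F-test, contrasts start and end concentrations
    with a linear model, and simulates destructive-sampling time-course
    datasets with the study design of a forest-versus-city ant exposure
    experiment so every stage can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
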