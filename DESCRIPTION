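Package: vasonet
Title: Synthesis and Biphasic Hemodynamics of Cortical Microvascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructive synthesis of cortical microvascular networks by
    constrained constructive optimization (CCO) with a meshed capillary bed,
    biphasic (red blood cell plus plasma) Poiseuille network hemodynamics with
    a kinetic plasma-skimming hematocrit split rule and diameter- and
    hematocrit-dependent blood viscosity, and cortical-layer analysis of the
    converged pressure, flow and hematocrit fields (flow-path tracing, layer
    statistics, RBC-flux variance, morphometric summaries and ensemble
    equivalence testing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
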