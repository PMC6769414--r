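Package: nidusflow
Title: Electrical-Network Hemodynamics of a Brain AVM Nidus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state hemodynamic simulation of a brain arteriovenous
    malformation (AVM) modeled as a resistive electrical network. Builds a
    three-dimensional nidus of plexiform and fistulous vessels fed by four
    arterial feeders and drained by three veins, solves the Hagen-Poiseuille /
    Kirchhoff flow system by sparse nodal analysis, simulates superselective
    angiography (SSA) pressure injections with optional occlusion of the other
    feeders, and detects intranidal hemodynamic compartments by Otsu
    thresholding of the per-vessel pressure-response distribution. Includes the
    accompanying computational experiments: the full SSA injection grid, a
    geometric (radius/length) sensitivity analysis, and a random-rewiring
    robustness ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    igraph,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
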