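Package: virtualfruit
Title: Biophysical Fruit Growth Simulation, Multi-Objective Calibration
    and Ideotype Design
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A process-based model of water and carbon accumulation in a
    growing fleshy fruit (turgor-driven expansion after Lockhart, xylem and
    phloem inflow through a pedicel and composite membranes; active,
    mass-flow and diffusive sugar uptake; respiration and transpiration),
    together with an NSGA-II multi-objective evolutionary algorithm used to
    calibrate genotype-specific parameters against fresh- and dry-mass time
    courses under control and water-deficit irrigation, and to design
    virtual genotypes (ideotypes) trading off dry-matter content against
    fresh-mass loss under water deficit. Includes a synthetic-population
    generator emulating a recombinant inbred line phenotyping design, and
    principal component / hierarchical clustering analysis of calibrated
    parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
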