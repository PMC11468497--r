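Package: micromix
Title: Design, Toolpath Generation and Mixing Analysis for Printed Passive Micromixers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing single-layer extrusion-printed passive
    micromixers and quantifying their mixing performance. Generates parametric
    channel centerlines (zigzag, variable-width V-zigzag, hexagonal, diamond
    and flow-focusing layouts), converts width-annotated centerlines into
    continuous variable-width extrusion toolpaths (Marlin-style G-code) by
    co-modulating extrusion rate and print speed, solves steady
    two-dimensional laminar flow and passive species transport on masked
    grids, computes field- and image-based mixing indices, advects tracer
    particles for velocity-profile validation, and builds fully synthetic
    dye-micrograph fixtures with known pixel classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
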