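Package: feedscreen
Title: Mechanical Feedability Screening for FDM 3D-Printing Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens hot-melt-extruded filaments for suitability in the
    feeding mechanism of fused deposition modelling (FDM) 3D printers.
    Reads force-distance flexibility profiles from a texture-analyzer
    compress-and-release test, resamples them onto a common grid,
    applies data-range normalization, and scores candidates by Pearson
    correlation against a library of known-feedable commercial reference
    filaments; the mean correlation score is rounded to a Boolean
    feedability call. A principal component analysis with varimax
    rotation sorts filament panels into feedable, tunable and
    non-feedable clusters. A physics-based simulator built on Euler
    column buckling generates labelled synthetic profiles for the four
    mechanical phenotypes observed on the instrument (sharp brittle
    fracture, strain-bearing brittle fracture, pliable buckling, floppy
    sub-trigger response) so the whole pipeline can be exercised and
    validated without a texture analyzer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    tibble,
    ggplot2,
    cluster,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
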