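Package: bvstereo
Title: Stereodynamic Analysis of Substituted Bullvalenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stereodynamics of substituted
    bullvalenes, the 'shapeshifting' C10H10 cage whose degenerate Cope
    rearrangements interconvert constitutional isomers.  Provides a ten-digit
    isomer barcode model with canonicalisation under the threefold scaffold
    symmetry, closed-form isomer counting with the C3 correction factor and
    an exhaustive enumeration oracle, chirality classification,
    Cope-rearrangement interconversion networks, template-based 3D structure
    generation with substituent grafting and force-field refinement (via
    Open Babel), principal-moment-of-inertia (NPR) and exit-vector shape
    descriptors, and Boltzmann population weighting of isomer ensembles.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel, obminimize and obenergy on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
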