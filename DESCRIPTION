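Package: fibroarrhythm
Title: Fibrosis Patterns, Spatial Entropy and Ventricular Arrhythmogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline linking the spatial texture of myocardial
    fibrosis to electrical instability in human ventricular tissue. Generates
    seeded diffuse, patchy and compact fibrosis label maps on regular tissue
    grids at exact fibrotic fractions, quantifies their spatial disorder with
    a Shannon fibrosis-entropy metric, simulates monodomain action-potential
    propagation with the ten Tusscher-Panfilov 2006 human ventricular ionic
    model under fibrotic ionic remodeling, induces reentry with an S1-S2
    cross-field protocol, classifies reentry sustainability across a
    conduction-velocity scan, counts phase singularities by topological
    charge, and correlates mean fibrosis entropy with phase-singularity
    burden across simulation ensembles.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
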