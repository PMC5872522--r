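Package: melnest
Title: Lattice-Based Individual-Based Model of Melanoma Nest Formation in Skin Co-Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates melanoma nest formation in a three-dimensional skin
    co-culture using a lattice-based individual-based model with volume
    exclusion. Adhesive, motile and proliferative melanoma agents interact
    with motile and proliferative skin agents on a 3D lattice with periodic
    lateral and no-flux vertical boundaries; melanoma motility is attenuated
    by a cell-cell adhesion modifier (1-q)^a, where a counts melanoma
    occupants of the Moore neighbourhood. Provides the stochastic update
    engine (random sequential update, motility then proliferation phases),
    nest quantification via wrap-aware connected-component labelling with a
    minimum-size filter and boxplot-style area summaries, scenario runners
    for proliferation- and adhesion-perturbation experiments, and
    configuration, snapshot and nest-table input/output with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
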