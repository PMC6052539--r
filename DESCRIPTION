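Package: shaperates
Title: Phylogenetic Rates of Body-Shape Evolution from Landmark Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of multivariate body-shape evolution on
    time-calibrated phylogenies. Parses 2-D landmark data in TPS format,
    performs generalized Procrustes superimposition, estimates multivariate
    Brownian-motion rates of shape evolution (sigma-squared) per clade and
    per phenotypic module (head vs. trunk), tests rate ratios against
    simulation-based null distributions, and projects species and
    ancestral-state estimates into a phylomorphospace. Includes a
    known-truth synthetic-study generator (two-clade chronogram, Brownian
    shape evolution, digitizing noise, nuisance rotation/translation/
    scaling) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
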