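Package: ontocolor
Title: Comparative Analysis of Ontogenic Colour-Defense Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies lifestage-versus-background colour contrast (delta RGB)
    from image palettes, classifies colour-defense strategies (masquerade,
    crypsis, aposematism), reconstructs ancestral defense states on a phylogeny
    by maximum-likelihood Mk fitting and stochastic character mapping, and tests
    host-plant and visual-background predictors of binary apparency with
    phylogenetic logistic regression (penalized maximum likelihood for the
    evolving-binary-trait model). Includes a seeded synthetic-data generator
    producing birth-death trees, correlated binary host characters and colour
    scenes with known ground truth, so every pipeline stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    png
Config/testthat/edition: 3
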