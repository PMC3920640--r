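Package: radtempo
Title: Tempo of Lineage and Morphological Diversification in Island Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-phylogenetics toolkit for testing whether an island
    radiation diversified early and rapidly, in both lineages and morphology.
    Implements the gamma statistic for the constant-rates test with a
    random-pruning null, likelihood fitting and AICc-weight ranking of
    pure-birth, time-varying pure-birth and constant-rate birth-death models
    on branching times (summarized across posterior tree samples),
    specimen-to-species morphometrics with size correction, ordinary and
    phylogenetic principal component analysis, ecotype MANOVA with a
    simulation-based phylogenetic null, disparity-through-time curves with
    the morphological disparity index (MDI) against Brownian-motion
    simulations, and Brownian-motion versus Ornstein-Uhlenbeck model
    selection for single characters. A synthetic-data generator produces
    ultrametric trees, posterior-like tree ensembles, clade-structured
    ecotype regimes and specimen-level measurement tables with the
    statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
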