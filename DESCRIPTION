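Package: sitesel
Title: Site-Level Selection, Conservation and Co-Evolution Analysis for
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for site-level molecular evolution analysis of
    protein-coding gene families: empirical-Bayes conservation profiling
    with sliding-window calling of highly variable regions (reverse
    conservation analysis), random-effects-likelihood codon models with a
    3x3 grid of discrete (dN, dS) rate classes and Bayes-factor detection
    of positively selected sites, and Bayesian-graphical-model detection
    of co-evolving sites from ancestral-reconstruction substitution maps.
    Includes a Felsenstein pruning likelihood engine over arbitrary finite
    state spaces, distance-based tree scaffolding (JTT maximum-likelihood
    distances, BIONJ, branch-length optimization, bootstrap), and seeded
    simulators for protein and codon alignments with gamma rate
    heterogeneity, site-specific selection classes and coupled
    co-evolving site pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
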