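Package: nestevo
Title: Evolution of Avian Nest Characters on Family Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian ancestral-state reconstruction of discrete nest
    characters (structure, site and attachment) under the Mk model across a
    set of family-level phylogenies, tests of correlated evolution between
    binary nest characters with harmonic-mean Bayes factors, and conventional
    plus evolutionary-model-based (EM-) Mantel tests of phylogenetic signal
    for multi-state, set-valued characters using Bray-Curtis dissimilarity.
    Ships seeded generators for synthetic trees, tree sets and discrete
    traits (including polymorphic tips and correlated binary pairs) so the
    full pipeline is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
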