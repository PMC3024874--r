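Package: herbnet
Title: Distance-Based Mutual Information Mining of Herb Combination Rules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mines pairwise combination rules from corpora of ordered
    multi-herb formulae using a distance-based mutual information model
    (DMIM): each formula is encoded as a normalized position vector, and
    herb pairs are scored by combining co-occurrence mutual information
    with the average within-formula distance between the two herbs.
    Builds weighted herb networks from top-ranked pairs, extracts
    chi-square-significant hub modules, and evaluates recovery of
    reference herb pairs.  Also implements a "co-module" analysis across
    herb-biomolecule-disease multilayer networks (Fisher-exact pathway
    enrichment with FDR control, permutation tests on average
    shortest-path closeness between gene sets in an interaction network,
    and cosine phenotype-similarity permutation tests), highest-single-
    agent synergy scoring for dose-matrix combination experiments, and a
    synthetic-data generator with planted herb pairs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
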