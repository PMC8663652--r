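Package: morphpars
Title: Maximum Parsimony Analysis of Discrete Morphological Character Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cladistic analysis of small discrete morphological
    character matrices: Fitch (unordered), Wagner (ordered) and irreversible
    parsimony scoring, exact (exhaustive and branch-and-bound) and heuristic
    (parsimony ratchet with tree-bisection-reconnection rearrangements) tree
    search, ensemble consistency and retention indices, nonparametric
    bootstrap clade support with strict-consensus counting, and unambiguous
    ancestral-state change mapping with synapomorphy/homoplasy
    classification. Reads and writes character matrices in plain table,
    NEXUS and TNT (xread) dialects, and bundles the morphological matrix of
    the harpacticoid copepod genus Bicorniphontodes (seven taxa, 41
    characters) on which every statistic the package computes can be checked
    end to end. A seedable simulator generates matrices of the same kind,
    including an irreversible state-gain model, for power and recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
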