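Package: dtlfix
Title: Species-Tree-Aware Gene Tree Error Correction Under
    Duplication-Transfer-Loss Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Error correction of maximum-likelihood gene trees for gene
    families affected by horizontal gene transfer. Implements undated
    parsimony duplication-transfer-loss (DTL) reconciliation of rooted and
    unrooted gene trees against a rooted species tree, a Shimodaira-Hasegawa
    (RELL) test of statistical equivalence between topologies under the JTT
    amino-acid model with discrete-gamma rate heterogeneity, and a
    hill-climbing NNI/SPR search that returns the tree of minimum
    reconciliation cost among those statistically equivalent to the input
    maximum-likelihood tree. Also provides the accompanying simulation
    framework (Yule species trees, a birth-death-transfer gene family
    simulator with recorded true event histories, and JTT+gamma sequence
    simulation) and evaluation utilities (normalized Robinson-Foulds
    distances, event-level precision and sensitivity against true
    histories), plus a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phangorn (>= 2.10),
    phytools,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
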