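Package: phyloprof
Title: Phylogenetic Profiling with Hierarchical Multi-Label Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene function from binary phylogenetic profiles
    (presence/absence of orthologous groups across genomes). Builds profile
    matrices from orthology-group membership tables, attaches Gene Ontology
    style annotations to profiles via a majority-of-members rule, trains a
    hierarchical multi-label classification random forest on the profiles,
    and scores per-term predictive accuracy by out-of-bag area under the
    precision-recall curve. Includes genome-subset selection strategies
    (random, greedy maximum phylogenetic diversity, clade, fixed list), a
    synthetic-data generator that simulates co-evolving gene modules by
    gain/loss along a species tree with incomplete annotations, and
    experiment drivers for annotation-fraction sweeps, genome-count sweeps,
    open-world-assumption controls and strain-redundancy controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
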