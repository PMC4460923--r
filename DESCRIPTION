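Package: adnet
Title: Disease-Gene Prioritization on Protein Interaction Networks with
    Alternating Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate disease genes from the topology of a
    protein-protein interaction network. Computes nine topological
    centrality measures plus the disease neighbor ratio for every
    protein, trains an alternating decision tree (ADTree) with
    confidence-rated boosting to separate disease-annotated from
    unannotated proteins, measures decision-rule conservation across
    bootstrap-trained trees, evaluates models by cross-validated ROC/AUC
    and feature ablation, and mines high-confidence false positives as
    novel disease-gene candidates together with the disease profile of
    their first- and second-order network neighbors. A synthetic-data
    generator produces interaction networks and planted disease-module
    annotations with the statistical structure of curated human data, so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
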