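Package: comorbnet
Title: Cross-Disease Molecular Linkage Analysis with Weighted Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying candidate molecular links
    between two diseases from transcriptomic and curated gene-disease data.
    Implements two-group differential expression with empirical-Bayes variance
    moderation, hypergeometric over-representation analysis with shared-term
    detection, weighted protein-protein interaction network construction from
    STRING-style edge tables, degree-based hub ranking, a weighted-degree
    ("comscore") leader-gene classification using exact one-dimensional
    K-means with ANOVA and Tukey-Kramer specific-class analysis, network
    merging with cross-talk gene extraction, and a from-scratch Molecular
    Complex Detection (MCODE-style) module finder with node-origin annotation.
    A synthetic-data module generates all inputs with planted ground truth so
    the whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
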