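Package: tagnorm
Title: DEG-Elimination Normalization and Benchmarking for Tag Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Between-sample normalization of tag count data (RNA-seq, ChIP-seq)
    by elimination of potential differentially expressed genes. Implements the
    three-step TbT strategy (trimmed-mean-of-M-values normalization, empirical
    Bayes identification of potential DEGs with bootstrap negative-binomial
    priors, renormalization of the DEG-free matrix) and its iterative
    refinement, together with a deterministic negative-binomial exact test for
    two-group gene ranking, a negative-binomial simulator with known
    differential-expression truth, and an AUC-based evaluation harness for
    comparing normalization/ranking combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Normalization, DifferentialExpression, RNASeq, Sequencing
RoxygenNote: 7.3.3
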