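Package: mirstage
Title: Stage-Wise miRNA Differential Expression and Regulatory Network
    Analysis for Tumour Progression Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for microRNA expression profiled across
    ordered clinical stages of a tumour (normal tissue through primary
    stages to lymph-node metastasis). Implements a random-variance-model
    moderated F-test for small-sample multi-group screening with
    Benjamini-Hochberg false discovery control, hierarchical clustering
    and classification of stage-trend trajectories into dynamic patterns,
    integration of predicted miRNA-target pairs with tissue-specific gene
    lists and inverse mRNA direction calls, hypergeometric gene-set
    over-representation analysis, IUPAC consensus motif scanning of
    pre-miRNA upstream regions to build TF-miRNA regulatory networks with
    correlation-weighted edges, detection of TF-miRNA-target negative
    feedback loops, relative qPCR quantification (2^-ddCt, standard-curve
    efficiency), and a synthetic-data generator that emulates the staged
    design for recovery benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    ape,
    jsonlite
Config/testthat/edition: 3
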