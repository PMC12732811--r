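Package: emtnet
Title: Consensus Hub-Gene Discovery and EMT-State Analysis in Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for identifying consensus hub genes of
    TGF-beta1-induced epithelial-mesenchymal transition (EMT) networks and for
    classifying, scoring, and validating EMT state in bulk, single-cell, and
    patient-cohort expression data. Provides two-group differential expression
    with empirical-Bayes variance moderation, construction of confidence-filtered
    interaction networks, twelve node-centrality metrics (including maximal
    clique centrality, DMNC, edge-percolation centrality, and BottleNeck),
    a top-fraction multi-metric consensus hub-calling rule across datasets,
    pre-ranked gene set enrichment analysis (GSEA) and single-sample ssGSEA,
    a single-cell stage (quality control, normalization, clustering,
    epithelial/mesenchymal classification, pseudobulk differential expression),
    Kaplan-Meier/log-rank survival stratification, and seeded synthetic-data
    generators that plant recoverable ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
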