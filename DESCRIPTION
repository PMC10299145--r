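Package: coexreg
Title: Co-Expression Network Clustering and Regulatory Gene Prioritisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene co-expression networks from RNA-seq
    count matrices (median-of-ratios normalisation, variance-based gene
    selection, soft-thresholded adjacency, topological overlap), detects and
    merges co-expression modules, and correlates module eigengenes with
    discrete developmental stages.  Hub genes feed an overlapping
    density-based graph clustering step (DPClusO-style greedy growth under
    density and cluster-property constraints); clusters are scored for
    regulatory-gene enrichment by the one-sided hypergeometric test, genes
    receive significance scores, and cluster sets across a density sweep are
    compared by ROC/AUC to prioritise candidate regulatory genes.  Includes a
    negative-binomial synthetic-data generator with planted modules and
    planted network clusters so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
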