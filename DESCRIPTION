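Package: samnet
Title: Permutation-Based Differential Expression and Network Ranking for
    Two-Group Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for two-group microarray studies: quantile
    normalization, significance analysis of microarrays (SAM) with a
    permutation null and q-value false discovery rate control, differential
    gene calling by joint q-value and signed fold-change thresholds, Fisher's
    exact gene-set over-representation with Benjamini-Hochberg correction, a
    directed pathway-interaction network ranked by node degree, and a typed
    gene signal network ranked by betweenness centrality. Ships a synthetic
    expression-data generator that emulates a balanced 6 versus 6 design with
    planted differential genes, enriched gene sets and network hubs, so the
    whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
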