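Package: rbscreen
Title: Differential Co-Expression Hub Scanning, Pooled shRNA Dropout
    Screens and Median-Effect Drug Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for three computations common in
    functional-genomics target discovery. (1) Differential hub
    co-expression scanning: network hubs whose Pearson correlation with
    their interaction partners differs between two conditions (for
    example tumour versus normal) are detected with a
    mean-absolute-correlation-difference statistic, label-permutation
    p-values and a subsample consensus over repeated runs, with
    edge-betweenness skeleton extraction and cross-species ortholog
    confirmation. (2) Pooled in-vivo shRNA dropout screens: per-sample
    count normalisation, log transformation, robust-Z (median/MAD)
    outlier-tumour exclusion, fold-change Z-scoring or log-ratio cutoff
    calling, gene-level hit tiering across cell lines and Fisher exact
    validation tests. (3) Median-effect (Chou-Talalay) drug-synergy
    quantification: fraction-affected computation, median-effect model
    fits, Combination Index and Dose Reduction Index for two-drug and
    pair-as-entity three-drug combinations, and potent-synergy
    classification. Synthetic-data generators with the statistical
    structure each stage assumes make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
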