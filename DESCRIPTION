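Package: hzexpr
Title: Hybrid-Zone Gene Expression Inheritance and Edaphic Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of hybrid-zone RNA-seq count data:
    trimmed-mean-of-M-values (TMM) normalization with FPKM computation,
    pairwise negative-binomial exact-test differential expression with
    Benjamini-Hochberg control, classification of hybrid transcripts into
    inheritance modes (conserved, additive, dominant, transgressive),
    soil-geochemistry ordination (PCA and regularized LDA), ridge latent
    factor mixed-model association of expression with an edaphic predictor
    including genomic-inflation calibration, and GO enrichment by the
    elim Kolmogorov-Smirnov method with information-content based
    redundancy reduction. Ships synthetic-data generators with known truth
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
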