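Package: tbphseq
Title: Target Prediction and Expression Analysis for a Fly TDP-43 RNA-Seq Study
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable, tested pipeline for analysing the transcriptomic
    consequences of manipulating TBPH, the Drosophila ortholog of the
    ALS-associated RNA-binding protein TDP-43. Provides UG-repeat motif
    scanning of genome annotations to predict binding-site genes, RPKM-based
    differential expression with genetic-rescue classification, splice-index
    screening and beta-binomial exon-junction statistics, hypergeometric
    set enrichment against custom backgrounds, and a conjugate Bayesian
    model of genetic-rescue survival from cross progeny counts. Ships a
    fully ground-truthed synthetic-data generator so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
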