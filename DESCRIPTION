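Package: casteDE
Title: Confidence-Interval Differential Expression Analysis of Bumblebee
    Larval Caste Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing caste-associated gene expression in
    bumblebee (Bombus terrestris) larvae across developmental stages.
    Implements subsampling (multivariate hypergeometric) normalization of
    read-count matrices, a replicate-interval differential expression
    caller with an offset fold change (OFC) effect-size statistic,
    classification of transcripts into annotation/novelty classes with an
    ORF-based coding call, reciprocal-best-hit orthology mapping,
    gene-list overlap testing with Bonferroni correction, and a qRT-PCR
    validation arm (inter-plate calibration, geNorm/BestKeeper reference
    stability, efficiency-corrected relative quantification, Mann-Whitney
    caste comparisons, and cross-platform congruence scoring). A
    synthetic-data generator emulating the six-phenotype study design
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
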