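Package: telotype
Title: Telomere Maintenance Mechanism Assessment from Sequencing and Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assessment of telomere maintenance mechanisms (TMM) in tumors,
    with a focus on neuroblastoma. Estimates telomere content from whole-genome
    sequencing reads, quantifies telomere variant repeat (TVR) composition and
    TVR singletons, detects intrachromosomal telomere insertions from discordant
    read pairs and telomeric soft-clipped alignments, and quantifies TERRA
    expression from RNA-seq reads. Quantifies the accompanying wet-lab assays:
    mean telomere restriction fragment (TRF) length from Southern-blot
    densitometry, C-circle assay calls under two published thresholds, and a
    Gaussian-mixture threshold for TERT expression. Samples are classified into
    telomerase-positive, ALT-positive and TMM-negative subgroups by a strict
    rule set, with ambiguous cases resolved by weighted multi-marker evidence;
    ROC curves with Youden-index threshold proposal and combined logistic
    predictors support threshold derivation. Seeded simulators generate every
    input the pipeline consumes so all stages are testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    mclust,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
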