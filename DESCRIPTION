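Package: senoscope
Title: Senescence Identity Scoring and Phenotype Analysis for
    Transcriptomic Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses cellular senescence from bulk and single-cell RNA-seq
    count matrices. Trains linear support-vector-machine classifiers with
    recursive feature elimination to derive senescence identity (SID)
    scores, maps decision values to probabilities by logistic calibration,
    and classifies senescent cells at a fixed 0.5 threshold. Scores
    senescence-related phenotype gene sets per sample with a gene-set
    variation statistic, orders cells along a senescence trajectory with
    held-out-gene validation via a graph-based pseudotime, and provides a
    benchmark harness (ROC, calibration curves, confusion matrices) plus a
    negative-binomial count simulator with planted ground truth. A
    command-line interface exposes the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
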