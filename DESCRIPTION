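Package: grnfuse
Title: Supervised Gene Regulatory Network Inference by Multiple Kernel Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-scale gene regulatory networks by fusing
    heterogeneous genomic data (expression, DNA methylation, protein-protein
    interaction graphs) into a combined positive semi-definite kernel and
    training one soft-margin kernel support vector machine per transcription
    factor. Per-factor subproblems are embarrassingly parallel and scored
    out-of-fold so that every gene receives a decision score from a model
    that never saw its label. Includes a seeded synthetic-genome generator
    with planted regulatory structure, precision-recall / AUC / AUPR network
    evaluation, and speedup/efficiency/redundancy/quality metrics for
    parallel runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
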