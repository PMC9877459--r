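Package: fflscope
Title: Transcription Factor-mRNA-miRNA Feed-Forward Loop Inference for
    Tumor Subtype Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage inference pipeline that goes from matched
    mRNA/miRNA expression cohorts to subtype-exclusive differentially
    expressed genes, clique-centrality hub genes, a correlation-validated
    transcription factor-mRNA-miRNA regulatory network with coherent
    feed-forward loops, and downstream immune-signature (ssGSEA,
    ESTIMATE-style) and survival (optimal-cutpoint log-rank, multivariate
    proportional hazards) characterization.  Includes a synthetic-cohort
    generator that plants the full regulatory, immune and survival
    structure so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
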