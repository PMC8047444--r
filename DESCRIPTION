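Package: naivexit
Title: Perturbation-Panel Analysis of the Exit from Naive Pluripotency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for dissecting how mouse embryonic stem cells
    exit the naive pluripotent state, built around a knockout-panel
    transcriptome design. Provides enrichment statistics for a haploid
    transposon insertional-mutagenesis screen (per-gene binomial test on
    TTAA integration opportunities), a threshold-based differential
    expression contrast engine with batch covariates, discovery of
    naive-associated genes by multiple regression on core marker responses,
    quantification of per-knockout differentiation delay by mapping fold
    change profiles onto a smoothed wild-type time course, 50-gene pathway
    expression footprints with directed activity scores, hierarchical
    response-module clustering with redundancy-reduced gene-set enrichment,
    pathway-to-module regression validated against temporal precedence in
    the time course, and fraction-of-identity deconvolution of bulk
    profiles against embryo reference stages. A synthetic-data module
    generates all inputs with planted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
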