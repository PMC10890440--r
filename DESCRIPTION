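Package: metabshift
Title: Longitudinal Metabolomic Association Scans and Differential
    Network Analysis for Weight-Loss Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing longitudinal untargeted plasma
    metabolomics in multi-arm weight-loss intervention cohorts.
    Implements treatment-by-metabolite interaction regression scans of
    percent-change glycemic outcomes (fasting plasma glucose, HbA1c)
    with pairwise intervention contrasts and Storey q-value false
    discovery control; sum-intensity normalization, group presence
    filtering and covariate residualization; weighted correlation
    network module detection via topological overlap with
    permutation-tested modular differential connectivity (gain/loss of
    connectivity calls) and hub identification; pathway
    over-representation by Fisher's exact test with a betweenness-based
    pathway impact score; and a synthetic cohort generator with planted
    interaction effects and group-specific correlation modules for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
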