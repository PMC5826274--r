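Package: songnet
Title: Behavior-Coupled Weighted Gene Coexpression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed weighted gene coexpression networks from bulk
    RNA-seq count matrices and relates their modules to continuous
    behavioral traits, following the workflow used to study vocal
    learning in the songbird basal ganglia. Covers TPM normalization and
    robust expression filtering, soft-threshold selection, topological
    overlap, iterative module detection with eigengene-membership rules,
    module-trait correlation with Fisher-transform p-values, permutation
    module-preservation statistics (Zsummary), term- and
    interaction-level prioritization, position-weight-matrix promoter
    scanning, and a fully seeded synthetic-data generator with planted
    modules for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    IRanges,
    mclust,
    readr,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
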