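Package: morphr
Title: Module-Partitioned Co-Expression Candidate Gene Prioritization (MORPH) in Bulk Mode
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the MORPH guilt-by-association algorithm for candidate
    gene prioritization from gene expression compendia: module-partitioned
    Pearson co-expression scoring of candidates against a bait gene set,
    within-module z-score standardization for a common ranking, leave-one-out
    self-rank cross-validation with area-under-the-self-rank-curve (AUSR)
    model selection across expression dataset x clustering configurations, and
    a genome-wide bulk mode with permutation-based empirical p-values,
    Benjamini-Hochberg correction, extended functional annotation, and
    cross-species comparative candidate networks built from orthogroup tables.
    Includes a synthetic-compendium generator with planted co-expression
    modules for end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    xml2
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
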