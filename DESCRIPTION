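Package: encore
Title: Combined Set- and Network-Based Gene Set Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression and gene set enrichment analysis for
    two-group expression studies, combining set-based methods
    (overrepresentation analysis, GSEA-style running-sum statistics, a
    SAFE-style sample-permutation framework, SAMGS-type sum-of-squares
    scores) with network-based scoring of regulatory-interaction
    consistency (GGEA-style), a generic plug-in contract for external
    enrichment methods, a rank-combination layer (absolute, relative and
    competitive ranks aggregated by sum, mean, median or min), a seeded
    synthetic-data generator for benchmarking, and a static HTML report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    purrr,
    readr,
    stats,
    tibble,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
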