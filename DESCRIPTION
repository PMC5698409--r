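Package: compartmeth
Title: Integrative Analysis of Chromatin Compartments and DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for studying how A/B chromatin
    compartments relate to DNA methylation during cell differentiation.
    Provides iterative (ICE) balancing of binned Hi-C contact matrices,
    A/B compartment inference by principal component analysis of
    observed/expected correlation matrices, multi-scale TAD insulation
    scores and boundary calling, CpG methylome segmentation into
    UMR/LMR/FMR/PMD classes, threshold-based differential methylation
    region (DMR) calling, CHH methylation binning, and
    compartment-methylation integration statistics with circular-shift
    permutation tests. A synthetic multi-stage cohort generator with
    planted ground truth makes every stage of the pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
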