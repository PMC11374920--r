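Package: oxtrace
Title: Quantitative Mapping of Oxytocin Fibers, Dense-Cored Vesicles and
    Receptor Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for semi-quantitative neuroanatomical mapping of the
    oxytocin system: ordinal staining scores are normalized into a Staining
    Density Index (SDI) per brain region, dense-cored vesicles (DCVs) measured
    in electron micrographs are classified as oxytocin-positive by a
    kernel-density-intersection size cutoff, per-profile DCV incidence is
    summarized with Wilson intervals, region-wise concordance between fiber
    density and receptor-transcript scores is assessed through an interaction
    linear model with per-category estimated linear trends, and RNAScope
    puncta counts are summarized per cell.  A synthetic-data module generates
    every input table with the stated distributional structure so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    withr,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    EBImage,
    readr
Config/testthat/edition: 3
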