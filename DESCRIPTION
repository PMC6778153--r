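Package: lfqpipe
Title: Label-Free Quantitative Proteomics Differential Abundance Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for label-free quantitative (LFQ)
    proteomics comparisons of two conditions with few replicates, modelled on
    the analysis of tomato fruit microsomal proteomes across ripening stages
    (mature green, MG30, versus red ripe, R45). Reads MaxQuant-style
    proteinGroups tables, applies identification-quality and valid-value
    filters with presence/absence (stage-specific) detection, imputes missing
    log2 intensities with a two-branch scheme (per-sample downshifted normal
    for sporadic missingness; average minimum log-intensity for
    condition-absent proteins), classifies proteins into abundance categories
    by fold change and false discovery rate, performs GO term
    over-representation against a background proteome, and correlates protein
    with transcript log2 fold changes globally and per functional class. A
    synthetic-data generator with known ground truth (log-normal intensities,
    intensity-dependent dropout, planted fold changes and class-specific
    mRNA-protein correlations) makes every stage verifiable without raw mass
    spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
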