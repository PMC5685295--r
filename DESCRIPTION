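Package: methylsilence
Title: Identify Genes Silenced by DNA Methylation from Array Methylation
    and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating Illumina 450K-style
    DNA methylation beta values with expression microarray intensities to
    identify genes silenced by CpG-island hypermethylation. Provides probe
    quality control, CpG island discovery and shore/shelf annotation,
    gene-level island methylation scoring, delta-beta-binned contingency
    analysis with a data-driven silencing threshold, silenced-gene
    classification for promoter and gene-body islands, cross-study
    concordance with external fold-change tables, Pfaffl-equation relative
    quantification for demethylation qPCR experiments, and a synthetic-data
    generator with known ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
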