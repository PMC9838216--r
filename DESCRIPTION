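Package: sfscreenr
Title: Secondary-Findings Screening for Consanguineous Genome-Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for screening annotated genome-sequencing
    variant tables against medically actionable gene-disease panels. Implements
    read-depth and allele-fraction variant QC, mode-of-inheritance-aware triage of
    pathogenic and likely pathogenic variants into primary findings, secondary
    findings (ACMG SF v3.1 and a custom actionability-scored panel) and carrier
    status, Human Phenotype Ontology based phenotype matching, cohort summary
    statistics with risk-ratio and odds-ratio estimates (Wald intervals, exact
    Fisher cross-check), and a synthetic-cohort simulator that models inflated
    homozygosity under parental consanguinity, including a deterministic
    reference cohort for end-to-end testing.
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
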