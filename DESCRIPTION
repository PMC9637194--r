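Package: methrelapse
Title: Longitudinal DNA Methylation Analysis of Serially Relapsing Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of CpG-level bisulfite methylation
    data across matched normal, primary, serial-relapse and patient-derived
    orthotopic xenograft (PDOX) samples. Calls per-site differential methylation
    against matched normal tissue with a Fisher exact test, classifies each
    site's trajectory over serial relapses into seven dynamic categories,
    discovers candidate relapse driver, booster and predictor sites, merges
    differentially methylated cytosines into regions and assigns them to genes
    by promoter proximity, filters candidates by PDOX preservation, integrates
    promoter methylation with gene expression through anticorrelation, and
    computes relapse-to-relapse convergence metrics. Includes a fully specified
    synthetic cohort generator with planted ground truth so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
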