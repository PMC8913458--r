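Package: liquidMRD
Title: Liquid-Biopsy Monitoring of Multiple Myeloma from Light-Chain
    Repertoires and Enriched-Plasma-Cell Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for minimal-residual-disease (MRD) monitoring of multiple
    myeloma from peripheral blood. Reads immunoglobulin light-chain (IGK/IGL)
    clonotype tables derived from cell-free DNA, applies read-depth quality
    control, estimates repertoire diversity with the bias-corrected Chao1
    index, identifies and tracks patient-specific myeloma clonotypes, and
    classifies samples into NGS result categories. Gates plasma-cell events
    in nine-marker flow-cytometry tables from magnetically enriched CD138+
    cells, scores immunophenotypic aberrancies, and categorizes samples by
    circulating-plasma-cell content. Cohort statistics link the two assays:
    repetitive-sample exclusion, response-group merging, cross-compartment
    clonotype overlap, Spearman correlation of clone frequencies, paired
    marker-intensity comparison with Holm-Sidak adjustment, and percent
    agreement with Cohen's kappa. A seeded synthetic-data module generates
    clonotype repertoires, paired-compartment samples, cytometry event
    tables, and named cohort fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
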