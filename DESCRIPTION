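Package: balproteo
Title: Consensus Biomarker Analysis of Bronchoalveolar Lavage Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Label-free quantitative proteomics analysis of bronchoalveolar
    lavage (BAL) fluid in lung-cancer cohorts. Provides a synthetic cohort
    simulator with abundance-dependent detection dropout and two correlated
    search-engine views across five quantitation types (spectral counts,
    LFQ, iBAQ at protein and peptide level); preprocessing by contaminant
    removal, log2(x+1) transformation, quantile normalization and Gaussian
    abundance filtering; empirical-Bayes moderated two-group differential
    expression with Benjamini-Hochberg control; a cross-engine consensus
    biomarker list and cancer-exclusive protein detection; PCA-based patient
    stratification with a separation-probability statistic; technical
    replicate and identification-saturation quality control; per-sample
    hypergeometric functional enrichment with category-level group tests;
    and gene-level multi-study consensus aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
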