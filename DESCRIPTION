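Package: exomarker
Title: Label-Free Proteomics Biomarker Discovery for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free mass-spectrometry proteomics
    biomarker discovery in case-control designs, modelled on urinary-exosome
    proteome studies. Turns peptide-level evidence into protein
    quantifications (spectral counts, Top3 precursor intensity, iBAQ with
    in-silico tryptic digestion), tests differential abundance between
    groups (presence/absence Fisher exact test, heteroscedastic t-tests on
    two quantification channels, pooled-replicate iBAQ validation), and
    evaluates candidate biomarkers (full-specificity detection thresholds,
    sensitivity, Youden's J, ROC curves and AUC, OR-rule and rank-score
    marker panels, focus-list filtering). Includes a seeded synthetic cohort
    generator with planted effects and detection-limit censoring so that
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
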