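Package: silis
Title: Stable-Isotope-Labeled Internal Standard Panels for Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and using stable-isotope-labeled (SIL)
    internal standard peptide panels in bottom-up plasma and serum
    proteomics. Selects analytically robust peptides from multi-study
    precursor quantification tables via a presence/CV weight-rank metric
    and physicochemical filters; concentration-matches a tiered SIL
    standard mixture to endogenous levels; performs SIL-ratio and median
    normalization with completeness and CV quality control; fits
    1/x-weighted calibration curves with LOD, LOQ, LLOQ and ULOQ
    determination; and runs a cross-matrix, cross-platform evaluation
    battery (Kendall trend tests with Benjamini-Hochberg adjustment,
    paired Wilcoxon tests, intraclass correlation, Bland-Altman
    agreement, random-effects variance partitioning with k-nearest
    neighbor imputation, composite-dataset construction, per-group
    regression, and PCA scores). Seeded synthetic-data generators
    emulate multi-study pool series, multi-platform clinical cohorts,
    and replicate calibration series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
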