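Package: rbcspec
Title: Semi-Quantitative Vibrational Spectroscopy of Red Blood Cells
Version: 0.1.0
Authors@R:
    person("rbcspec", "developers", email = "rbcspec@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for semi-quantitative vibrational
    biospectroscopy of red blood cells and their membranes. Reads FTIR-ATR
    and Raman spectral tables (two-column text and a JCAMP-DX-like dialect),
    preprocesses them (cosmic-ray despiking, Savitzky-Golay smoothing and
    second derivatives, rubberband or polynomial baseline removal, vector
    normalization, optional first-order ATR penetration-depth correction),
    integrates a library of lipid and protein marker bands, and summarises a
    biomarker ratio panel (phospholipid content, lipid unsaturation, acyl
    chain shortening, cholesterol esters, esterified lipids, total protein,
    amide II/amide I, and amide I second-derivative secondary-structure
    ratios) per group with exact Mann-Whitney testing. Companion tools cover
    ektacytometry elongation indices, red-cell indices derived from complete
    blood counts, and a fully seeded synthetic cohort generator so every
    stage of the pipeline is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
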