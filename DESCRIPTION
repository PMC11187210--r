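Package: imodmatch
Title: Matched Transcriptome-Proteome iModulon Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Modularization of matched bacterial transcriptome and proteome
    compendia into independently modulated gene sets (iModulons). Provides
    label-free absolute protein quantification from top3 peptide intensities
    calibrated against a UPS2 spike-in standard, quality-controlled compendium
    assembly (coverage filtering, minimum imputation, log2(PPM+1) transform,
    replicate concordance filtering, reference-condition centering), robust
    independent component analysis with consensus clustering over restarts,
    gene-weight thresholding and regulator enrichment, cross-omics module
    matching with differential membership (DiMM) and activity (DiMA)
    comparisons and regulatory-dominance classification, and cross-validated
    regression (linear, exponential, broken-line) that infers proteome mass
    allocation from transcriptome module activities. A seeded synthetic-data
    generator with planted module structure makes every stage verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
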