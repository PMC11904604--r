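Package: mrmquant
Title: Isotope-Dilution MRM Quantitation of C-Peptide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for a multiple-reaction-monitoring (MRM)
    liquid chromatography-mass spectrometry assay of serum C-peptide based on
    Glu-C digestion and isotope dilution. Provides in-silico protease
    digestion, b/y fragment-ion mass calculation and MRM transition-table
    design for native/13C6-labeled peptide pairs, a synthetic chromatogram
    simulator with peak detection and trapezoidal integration, response-ratio
    quantitation against a two-point calibration traceable to a certified
    reference material, qualifier-ion-ratio and retention-time quality
    control, and an assay-validation suite (precision variance components by
    one-way ANOVA, CV-profile lower limit of quantitation, linearity,
    interference recovery, stability change, and method-comparison
    regression including Deming).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
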