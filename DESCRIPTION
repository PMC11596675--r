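Package: nadomics
Title: Isotope-Dilution Matrix-Matched Quantification of the NAD Metabolome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for absolute quantification of NAD+ and its precursors,
    redox partners and degradation products (the "NADome") from targeted
    LC-MS/MS multiple-reaction-monitoring (MRM) peak areas. Implements
    13C isotope-dilution response ratios with surrogate internal standards,
    matrix-matched least-squares calibration with background subtraction,
    slope-based limits of detection and quantification (LOD = 3.3*sigma/S,
    LOQ = 10*sigma/S), natural-abundance isotopologue distributions and MRM
    channel crosstalk screening, precision/accuracy/stability validation
    metrics, cell-dry-weight normalization with Dixon's Q outlier filtering,
    bioreactor physiology kinetics (growth rates, specific rates, yields,
    respiratory quotient), and downstream statistics (redox ratios, log2
    fold changes with ANOVA/Tukey/FDR, autoscaled PCA). A seeded synthetic
    MRM-data generator reproduces the statistical structure the pipeline
    assumes so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
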