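Package: circadia
Title: Circadian Locomotor Rhythm Analysis and Label-Free Proteomics
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the analysis of wheel-running and Drosophila
    locomotor activity rhythms under complex light schedules: chi-squared
    (Sokolove-Bushell) periodograms, FFT rhythm strength, activity onset
    detection, regression-based free-running period, phase-shift and
    phase-angle measures, jetlag re-entrainment kinetics, anticipation
    indices, and rhythmicity/internal-desynchrony classification.
    Includes an entrainable phase-oscillator simulator of activity counts
    and a Perseus-style label-free proteomics workflow (flag filtering,
    log2 transform, downshifted-normal imputation, S0-modified two-sample
    t test with Benjamini-Hochberg FDR, Fisher's exact term enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
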