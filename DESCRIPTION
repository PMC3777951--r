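Package: cardiofp
Title: Field-Potential Analysis for Cardiomyocyte Micro-Electrode-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic analysis of extracellular field potentials recorded
    from spontaneously beating cardiomyocyte aggregates on micro-electrode
    arrays (MEA), in the context of drug cardiotoxicity screening. Reads
    MC_DataTool-style ASCII exports, attenuates noise with a zero-phase
    Butterworth filter, detects depolarization peaks, classifies per-beat
    field-potential complexes against a template by lagged cross-correlation,
    ensemble-averages the accepted complexes, locates repolarisation onset and
    offset (trapezium-area method) and reports field potential duration (FPD),
    Bazett rate-corrected FPD, area under the curve and beating rate. Includes
    a confusion-matrix validation framework for the template classifier, an
    overlay comparison of drug-concentration series, a deterministic synthetic
    recording generator with exact ground-truth landmarks, and a command-line
    interface.
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
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
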