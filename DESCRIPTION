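Package: sdoptics
Title: Optical Diagnosis of Shock-Wave-Induced Spreading Depolarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fiber-based diffuse reflectance spectroscopy
    and intrinsic optical imaging of the rodent cortex exposed to a laser-induced
    shock wave. Implements forward Monte Carlo photon transport in layered tissue
    for a source-detector fiber pair, regression-based inversion of reflectance
    spectra to hemoglobin concentrations, scattering amplitude and oxygen
    saturation (StO2) via a pre-computed conversion model, ratiometric band
    signals and event detectors for spreading-depolarization physiology
    (scattering transients, EEG suppression, DC potential shift, long-lasting
    hypoxemia, heme aa3 reduction), wavefront speed estimation from image stacks
    and multichannel onset regression, cohort event tallies, and synthetic-data
    generators that emulate every input modality.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
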