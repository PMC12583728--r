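Package: thermobuzz
Title: Thermal Performance of Bumblebee Non-Flight Thoracic Vibrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing accelerometer recordings of bumblebee
    defensive buzzing and the thermal ecophysiology of the indirect flight
    muscles that power them. Provides buzz segmentation from raw
    acceleration traces, smoothed peak-acceleration and cepstral
    fundamental-frequency estimation, per-bee aggregation, allometric
    scaling tests against the isometric exponent, linear mixed-effects
    models of buzz biomechanics with Type III tests and Satterthwaite
    degrees of freedom, quadratic thermal-performance curves with
    bootstrap confidence intervals for the performance peak, and
    sigmoidal air-to-thorax thermoregulation fits compared against linear
    alternatives. A seeded synthetic-data module generates harmonic buzz
    waveforms and bee-level datasets with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    lmerTest,
    minpack.lm,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
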