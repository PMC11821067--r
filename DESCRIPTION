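Package: sifband
Title: Evaluation of Solar-Induced Chlorophyll Fluorescence Retrieval at
    Atmospheric Absorption Bands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating solar-induced chlorophyll fluorescence
    (SIF) retrieval algorithms at the 719 nm water-vapor absorption band
    and the O2-B and O2-A bands. Provides a synthetic scene emulator
    (canopy reflectance, two-peak fluorescence emission, downwelling
    irradiance with parametric water-vapor and oxygen absorption lines),
    an instrument model (Gaussian line-shape convolution, resampling, and
    signal-to-noise dependent Gaussian noise), seven retrieval algorithms
    (sFLD, 3FLD, iFLD, pFLD, spectral fitting, singular-vector regression,
    and DOAS log-ratio fitting), an accuracy and sensitivity-sweep
    harness, and a processing pipeline for tower-based alternating
    irradiance/radiance time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
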