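Package: vhitools
Title: Satellite Vegetation Health Indices, Drought Statistics and ENSO
    Teleconnection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the satellite-based vegetation health indices (VCI,
    TCI, VHI) from weekly gridded NDVI and brightness-temperature fields,
    classifies drought intensity and derives percent-area-affected and
    duration statistics, estimates trends (OLS, Mann-Kendall, Sen's
    slope), and analyses linear and wavelet-based (cross wavelet
    transform, wavelet coherence with AR(1) red-noise Monte-Carlo
    significance) teleconnections between vegetation condition and an
    ENSO index. Includes a synthetic weekly-cube generator so the whole
    pipeline runs end-to-end without external archives.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
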