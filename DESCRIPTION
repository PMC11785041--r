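Package: xrfres
Title: Single-Image Resolution Estimation for Scanning X-Ray Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the achieved spatial resolution of scanning fluorescence
    X-ray microscopy (SFXM) elemental maps from a single image using power
    spectral density analysis: a power-law fit of the signal trend, a flat
    Poisson noise floor, and a Rose-criterion (signal-to-noise ratio 5)
    resolution frequency. Supports azimuthal-sector analysis for directional
    resolution, Wiener filtering of photon-limited maps, closed-form beamline
    photometry (absolute flux from a calibrated photodiode, detector solid
    angle, effective beam width under tilt, detector distance from
    inverse-square measurements, fluence per time), and a synthetic-map
    generator with known power-law spectra and Poisson counting noise for
    validation. Reads elemental maps from HDF5, TIFF, or delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
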