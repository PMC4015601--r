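Package: thermotrack
Title: Rotation-Tolerant Region Tracking and Virtual Temperature Sensing
    for Thermal Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Contactless "virtual thermal sensor" pipeline for infrared
    thermography of neonates in incubators. Tracks rectangular regions of
    interest across thermal image sequences with a rotation-invariant
    ring-projection-transform matcher, a scale-tolerant parametric
    (multi-scale) template with closed-form Lagrange-multiplier weights,
    and a plain normalized-cross-correlation baseline. Extracts per-region
    skin-temperature time series with radiometric emissivity/transmission
    correction, generates synthetic thermal phantoms with scripted motion
    and known ground truth, and scores tracking quality against that
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
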