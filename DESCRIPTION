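Package: ybrems
Title: Energy-Resolved Bremsstrahlung Imaging for Yttrium-90 Radioembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models energy-resolved bremsstrahlung imaging of yttrium-90
    liver radioembolization with a stationary gamma camera. The recorded
    x-ray energy encodes source depth through water attenuation: after
    normalization, the projection measured in a detector pixel is the
    Laplace transform in depth of the activity-times-efficiency profile
    along the collimator line of response. The package provides the
    bundled photon cross-section tables, parallel-hole and pinhole
    line-of-response geometry, the energy-resolved forward projector, the
    regularized numerical inversion of the Laplace transform, a slab
    photon-transport Monte Carlo for scintillator full-energy absorption
    efficiency, the BGO temperature gain-calibration procedure, and
    synthetic phantom and acquisition generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
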