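Package: nbkit
Title: Nanobubble Characterization and Ultrasound-Enhanced Uptake Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing sub-micron lipid-shelled bubble
    (nanobubble) populations and quantifying ultrasound-enhanced drug
    uptake on microfluidic chips. Implements closed-form flotation
    (Stokes terminal rise), Rayleigh scattering and transducer beam-spread
    models; size-distribution analytics for nanoparticle-tracking (NTA)
    exports including a camera-level detection model that discriminates
    gas-filled bubbles from liposomes; exponential decay fitting for
    bubble stability with free-lipid and interbubble-spacing
    interpretation; and a confocal fluorescence pipeline producing a
    total-fluorescence-intensity (TFI) uptake metric from two-channel
    tile scans. A seeded synthetic-data module generates every input
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    Matrix,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
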