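Package: cakefilter
Title: Retinal Vessel Segmentation with Quadrature Cake Filter Banks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of retinal blood vessels in fundus photographs using a
    bank of quadrature "cake" filters constructed in the two-dimensional Fourier
    domain. Each filter occupies a wedge-shaped angular sector (a B-spline angular
    profile times a Gaussian-over-truncated-Taylor radial profile), and the bank
    of N rotated wedges tiles the frequency plane. Per-orientation complex
    responses (orientation scores) are fused by a per-pixel minimum of their real
    components, and the vessel network is extracted with an adaptive histogram
    threshold. Includes pixel-wise evaluation metrics (accuracy, true and false
    positive rates), deterministic synthetic vessel phantoms with ground truth so
    the whole pipeline is testable without external data, image I/O for
    PPM/PNG/TIFF/JPEG, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    jpeg,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
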