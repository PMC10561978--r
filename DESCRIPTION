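Package: stomakit
Title: Anchor-Free Rotated Stomata Detection and Maximum Stomatal Conductance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and measurement of rotated (oriented) stomata in leaf
    epidermis micrographs with an anchor-free keypoint-heatmap convolutional
    detector, and calculation of anatomical maximum stomatal conductance
    (g_smax) from the measured traits. Provides a synthetic epidermis image
    generator with exact rotated-box ground truth, annotation I/O, the
    preprocessing and augmentation pipeline (border padding, grayscale
    stretching, rotation with label transforms, the two-thirds visibility
    rule), a deep-layer-aggregation backbone with channel/spatial attention
    and four prediction heads (center heatmap, size, sub-pixel offset,
    orientation angle), a five-term training loss including a stomatal
    conductance term, rotated-box decoding via 3x3 max-pool peak extraction,
    rotated-IoU evaluation, and an AdamW training loop with exponential
    learning-rate decay. The network and its training are implemented on a
    small reverse-mode automatic differentiation engine using BLAS-backed
    im2col convolutions, so the whole pipeline runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
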