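Package: phenovine
Title: Image-Based Grapevine Drought Phenotyping from 3D Point Clouds and
    Multi-View RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drought responses of potted grapevines from imaging
    data. Extracts 3D leaf angles from colored point clouds via color-based
    noise filtering, region-growing organ segmentation and total-least-squares
    blade-plane and petiole-line regression; computes 2D RGB indices
    (projected shoot area over one top and three side views, and the HSI-hue
    greener fraction); fits and cross-validates the linear calibration of
    total leaf area on projected shoot area; and generates fully seeded
    synthetic plants with known ground truth to exercise the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
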