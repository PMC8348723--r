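Package: clockscore
Title: Automatic Qualitative Scoring of Digitized Clock Drawing Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores digitized Clock Drawing Tests (CDT) from time-stamped
    touch-sensor traces and raster drawings. Implements stroke extraction
    from down/move/up touch-event streams, contour geometry (bounding box,
    bisecting center, least-squares circle fit, closure distance), canonical
    digit anchor positions, connected-component digit cropping with
    pluggable classification backends, Ratcliff-Obershelp drawing-order
    similarity, hand-line clustering and target-number indication tests, and
    the 13-criterion qualitative score (contour 0-3, numbers 0-4, hands 0-5,
    center 0-1). Includes reproducible U-Net and CNN architecture builders
    with a smoke-scale training harness, oracle segmentation and
    classification backends, and a synthetic clock-drawing generator with a
    parametric defect catalogue so every pipeline stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
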