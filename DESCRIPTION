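Package: telotrack
Title: Adaptive Eight-Sector Mean-Shift Tracking of Cells in
    Phase-Contrast Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tracks individual cells in phase-contrast time-lapse
    sequences by an intensity-weighted mean-shift procedure built on a
    pair of concentric eight-sector polygonal kernels: a white kernel
    attracted to the bright halo and a black kernel attracted to the
    dark cell body. Sector membership is decided by exact triangle
    geometry with even-odd ray casting, and the eight sector radii adapt
    each frame from the distances of per-sector foreground weight
    centers. Includes the histogram-equalization and local-threshold
    preprocessing chain, a seeded synthetic-sequence generator with
    exact ground truth for validation, a small query-by-example image
    retrieval component based on gray histograms and shape-moment
    descriptors, and readers/writers for TIFF/PNG sequences and
    trajectory tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
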