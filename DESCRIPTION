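Package: micropick
Title: In Silico Micropipette Single-Cell Isolation with Computer Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and image-analysis toolkit for computer-vision
    controlled micropipette single-cell isolation from a thin layer of cell
    suspension. Provides a synthetic-imaging module that renders fluorescent
    microscope frames and mosaics of known cell populations, a local-variance
    blob detector with brightness and size gating plus import of external
    (ImageJ Analyze Particles) segmentations, adaptive re-targeting of cells
    that drift between scanning and picking, greedy pick-and-place route
    planning with timed pressure/valve protocols, and a stochastic digital
    twin of the suspension (persistent random-walk cell floating,
    capture-radius pick physics with nanoliter volume accounting, deposition
    spread, and microwell-array trapping). Workflow drivers reproduce sparse
    single-cell isolation, successive enrichment of rare labeled cells from
    dense cultures, and the microwell-entrapment comparison entirely in
    silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
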