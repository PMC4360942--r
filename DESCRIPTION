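Package: photonsim
Title: Photon-Calibrated Optical Sectioning for Structured Illumination
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Converts raw three-phase structured illumination microscopy
    (SIM) image triplets into photon-calibrated wide-field and optically
    sectioned images with per-pixel noise maps, in 2D and 3D.  Camera
    gain and read noise are calibrated from flat-field image pairs by the
    photon-transfer method, and the illumination modulation contrast is
    estimated from a thin fluorescent bead field.  Includes a
    synthetic-data simulator with a Monte-Carlo ensemble oracle, TIFF
    input/output for row-concatenated phase triplets and multi-page 3D
    stacks, a human-readable calibration file format, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
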