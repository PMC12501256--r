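Package: sptherm
Title: Single-Pixel Thermal Imaging with Cyclic S-Matrix Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and reconstruction toolkit for single-pixel
    long-wave-infrared thermometry. Builds binary cyclic S-matrices by the
    twin-prime quadratic-residue construction, lays their two-dimensional
    encoding patterns out as a diagonally aggregated scanning stripe,
    simulates compressed bucket-signal acquisition from synthetic thermal
    scenes, recovers images non-iteratively via discrete Laplace
    interpolation of unmeasured signals followed by the closed-form
    S-matrix inverse, and calibrates reconstructed intensity against
    blackbody temperature sweeps to produce temperature maps. Includes
    phantom generators (uniform fields, dot-matrix letters, sub-pixel
    slits, inner-canthi-like hot spots), sampling-uniformity and
    spatial-resolution metrics, and plain-text file export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
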