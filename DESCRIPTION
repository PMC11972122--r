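Package: s2map
Title: Secretion-Signal Map Analytics for Single-Cell Secretion Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Position-aware inequality analytics for two-dimensional
    single-cell secretion maps. Implements the unsorted Lorenz-curve degree
    of inequality (DI) and the center-weighted signal-to-noise ratio (CWSNR)
    for one-dimensional signal profiles, their rotation-robust 2D composites
    (the signal inequality index, SII, and the signal coverage index, SCI),
    comparator concentration indices (Shannon entropy, Theil, Herfindahl-
    Hirschman, Simpson, Atkinson), spatiotemporal diffusion simulators,
    an end-to-end time-series secretion pipeline (block aggregation, window
    averaging, baseline correction, noise cutoff, metric series, Pearson
    comparison and secretio-type clustering), multi-layer map rendering,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
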