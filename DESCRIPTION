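Package: microed
Title: Processing of Micro-Electron-Diffraction (MicroED) Tilt Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reducing three-dimensional electron-diffraction
    (MicroED) tilt series collected from sub-micron protein crystals in a
    cryo-electron microscope: electron-optics and detector geometry,
    difference-vector autoindexing with orthogonal-triplet search, Ewald
    zone-based reflection prediction, square/circle mask intensity
    integration, Laue-symmetry merging with the maximum-intensity rule, and
    plain-text structure-factor export.  A forward simulator generates
    synthetic tilt-series frame stacks with ground-truth reflection tables
    from a known unit cell, orientation and electron-dose protocol, so the
    whole processing chain is testable without instrument data.  Includes
    radiation-dose accounting with critical-dose detection, systematic-
    absence leakage diagnostics for dynamic scattering, and per-frame
    attainable-resolution curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
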