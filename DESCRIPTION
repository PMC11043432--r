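Package: gridclock
Title: Grid-Like Coding Analysis for Imagined Clock-Space Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting n-fold rotational symmetry (grid-like
    coding) in entorhinal fMRI signals during imagined navigation of a
    clock-face environment. Generates fully counterbalanced session
    designs on a dodecagonal clock space, simulates voxel time series
    with planted directional tuning, fits cross-validated quadrature
    -filter general linear models to estimate grid orientation and
    held-out sinusoidal modulation strength, provides circular
    statistics (Rayleigh uniformity test) for orientation clustering,
    scores a real-world path-integration task, and assembles
    group-level statistical reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
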