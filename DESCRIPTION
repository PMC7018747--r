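Package: tiltbench
Title: Benchmarking Cryo-ET Tilt-Acquisition Schemes by Simulated Subtomogram Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating and benchmarking cryo-electron tomography
    tilt-acquisition schemes at desk scale. Generates continuous, bidirectional
    and dose-symmetric (Hagen) tilt-schemes, including dose-symmetric variants
    with decreasing or increasing angular increments, with per-projection
    exposure bookkeeping. Provides an analytic information-transfer model
    combining critical-exposure dose attenuation with tilt-dependent effective
    specimen thickness, a synthetic virus-like-particle phantom and tilt-series
    simulator (CTF, cumulative-dose filtering, controllable alignment error),
    weighted-backprojection reconstruction, a simplified subtomogram-averaging
    workflow with symmetrized half-map averaging, lattice particle cleaning
    (ellipsoid fitting, distance cleaning, per-particle bookkeeping),
    gold-standard Fourier shell correlation with phase randomization, B-factor
    analysis, best-tomogram subset selection, and alignment-error injection
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
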