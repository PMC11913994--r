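Package: ionopt
Title: Design-of-Experiments Optimization of ESI Source and Collision-Cell
    Parameters for LC-MS/MS Oxylipin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for systematic optimization of electrospray-ionization
    source and collision-cell settings of a triple-quadrupole LC-MS/MS
    method for oxylipin quantification.  Implements the full
    design-of-experiments workflow: resolution-IV fractional factorial
    screening with alias-structure bookkeeping, central composite designs
    with rounded and hard-bound-clipped axial points, D-optimal designs by
    Fedorov coordinate exchange, per-analyte quadratic response-surface
    models with PRESS-based predictability, reproducibility and
    lack-of-fit diagnostics, Monte-Carlo design-space mapping with a
    weighted multi-response failure criterion, collision-energy refinement
    against one-factor-at-a-time scans, and 1/x-weighted calibration with
    signal-to-noise and back-calculated-accuracy based limits of
    quantification.  A seeded synthetic-instrument module generates
    response tables and dilution series from committed ground-truth
    response surfaces so the whole pipeline can be exercised and validated
    without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
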