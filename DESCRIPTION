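Package: gridspike
Title: Spike-Level Grid Scores and Orientations for Spatial Firing Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the local hexagonal symmetry of two-dimensional
    neuronal firing patterns, one spike at a time. Each spike of a grid-cell
    recording receives a grid score and an orientation derived from the
    crystallographic M-fold bond-orientational order parameter, computed over
    neighbors in an automatically detected annular shell and guarded against
    competing symmetries. Includes the conventional autocorrelogram-based
    grid score as a reference, shuffling-based grid-cell classification with
    per-cell thresholds, spatially and temporally local score aggregation,
    and a synthetic spike-map generator with controlled perturbations
    (field jitter, shearing, background spikes, orientation changes,
    temporal regime switches) for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
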