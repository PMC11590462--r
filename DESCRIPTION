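Package: movresid
Title: Movement Strategies and Residency Analysis for GPS-Tracked Waterbirds
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying movement strategies of GPS-tracked animals,
    built around continuous-time movement models. Includes an exact simulator
    for Ornstein-Uhlenbeck-Foraging (OUF) resident movement, nomadic and
    diel-structured synthetic tracks with known ground truth; telemetry
    preprocessing (fix parsing, track filtering, regularization onto a common
    6-hourly grid, monthly segmentation); distance statistics (roost-to-forage
    distance, roost shifts, cumulative travel rates) with percentile-based
    permutation tests; empirical semivariance estimation, weighted
    least-squares OUF variogram fitting, and derivative-based monthly
    residency classification; autocorrelated kernel density estimation (AKDE)
    of residency areas with 95% contours, Bhattacharyya-coefficient overlap
    with parametric-bootstrap confidence intervals, and merging of overlapping
    months into residency blocks; residency odds with delta-method confidence
    intervals and seasonal two-proportion permutation tests; and
    site-revisitation statistics against user-supplied wetland polygon layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
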