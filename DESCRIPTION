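Package: spikespline
Title: Point-Process GLMs for Spike Trains with Boundary-Modified Cardinal Splines
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for fitting point-process generalized linear models to neural
    spike trains, with an emphasis on cardinal (Catmull-Rom-type) spline bases and
    a boundary-modified variant that assumes a flat derivative at the endpoint
    knots. Provides basis construction (cardinal, modified cardinal, raised-cosine,
    indicator), spatial and spike-history design matrices, maximum-likelihood
    fitting by iteratively re-weighted least squares with observed Fisher
    information, Wald confidence intervals for parameters and intensity curves,
    complete-separation detection, the confidence-interval width ratio (CIWR)
    boundary diagnostic, time-rescaling goodness-of-fit, and a synthetic place-cell
    session simulator with refractory, bursting and theta-band history structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
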