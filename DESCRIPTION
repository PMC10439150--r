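Package: refcurve
Title: Automated Continuous Reference Intervals and Percentile Charts from
    Routine Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automated estimation of continuous, age-dependent
    reference intervals and percentile charts from mixed routine laboratory
    measurements (non-pathological plus pathological).  The pipeline builds
    overlapping high-resolution age groups, fits a Box-Cox transformed
    normal model of the non-pathological bulk in each group by multi-level
    grid search, converts the fitted models into per-measurement
    probabilities of being non-pathological via a smoothed density ratio,
    and estimates smooth age-dependent distribution parameters (BCCG, BCPE
    or BCT families) by weighted penalized maximum likelihood with
    BIC-based selection of both smoothing strength and distribution family.
    The fitted model yields percentile charts, z-scores, and bootstrap
    confidence bands.  A seeded synthetic-data generator with closed-form
    truth percentiles supports validation without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
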