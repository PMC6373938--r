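Package: premcal
Title: Psychometric Calibration and Adaptive-Test Simulation for
    Patient-Reported Experience Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Develops and validates polytomous patient-reported experience
    measures with the partial credit Rasch model.  Provides non-parametric
    Mokken screening (Loevinger scalability, monotonicity, parallel
    polychoric principal component analysis), marginal maximum likelihood
    calibration with EAP scoring, an iterative item-purification pipeline
    (category-threshold collapsing, Yen's Q3 local dependency, hybrid
    ordinal-logistic-regression differential item functioning, misfit
    removal), test-retest agreement via Bland-Altman limits, and
    fixed-length computerized adaptive testing simulation with maximum
    posterior weighted information item selection.  Includes a synthetic
    response generator emulating a mental-health physical-care-planning
    experience survey, and the published 19-item calibrated bank for that
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
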