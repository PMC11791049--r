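Package: twingaze
Title: Twin-Design Analysis of Infant Gaze Behaviour on Dynamic Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for twin studies of infant eye
    movements during free viewing of dynamic naturalistic and abstract scenes.
    Provides a synthetic-data generator for twin cohorts with known ACE/ADE
    (co)variance structure and 120 Hz gaze streams; an adaptive velocity-threshold
    fixation classifier with duration and precision filters; dynamic
    area-of-interest scoring of face and active-actor looking; data-quality
    screening and residualization; univariate and bivariate Cholesky twin models
    estimated by full-information maximum likelihood with support for partially
    complete pairs; and cluster-robust (independence-working GEE) association
    analyses including simulated polygenic-score predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
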