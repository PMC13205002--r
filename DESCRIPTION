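Package: pcsrank
Title: Subject-Informed Ranking of Fingertip Electrotactile Electrode
    Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quasi-static electric fields in a four-layer fingertip
    skin model under 3 x 2 disc-electrode arrays, drives a passive
    myelinated-fiber (SENN-style) cable model with the extracellular
    potentials, scores each of 36 candidate electrode diameter-spacing
    geometries with the Perceived Correctness Score (PCS), and ranks
    configurations per subject with a cross-validated gradient-boosting
    regressor. Includes a synthetic psychophysics generator emulating
    5-alternative pattern-recognition experiments so the full
    predict-then-verify workflow can be exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    caret,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
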