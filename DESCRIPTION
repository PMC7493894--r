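Package: apoptimer
Title: Cooperative Apoptosome Recruitment, the Caspase-9 Molecular Timer
    and XIAP in Apoptosis Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation modelling of the
    apoptosis execution phase with cooperative pro-caspase-9 recruitment to
    the apoptosome, the molecular timer formed by autocleavage to
    weakly-binding caspase-9 p35/p12, and regulation by XIAP and SMAC.
    Includes extraction of binding kinetics from dissociation traces,
    global calibration against substrate-cleavage and timer training data,
    APAF1 x PC9 grid screens of IETDase activity, virtual-cell cohort
    screens (Kaplan-Meier survival, logrank, ROC, Webb's fractional-product
    synergy) after full and minority mitochondrial outer membrane
    permeabilisation, and apoptosis-competency classification of patient
    protein profiles with survival analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    survival,
    lhs,
    pracma,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
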