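Package: kneeplan
Title: Surgeon- and Patient-Specific Preoperative Planning for Total Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns surgeon-specific corrections to manufacturer default preoperative
    plans for total knee arthroplasty. A plan is 14 degrees of freedom (7 femoral,
    7 tibial) on 0.5 mm / 0.5 degree / ordinal-size grids. Per-case anatomical
    features (landmark coordinates in anatomical frames, implant-fit measurements,
    default-plan parameters) feed sparsity-based feature selection (Lasso, group
    Lasso, Multi-Task Lasso, all solved by coordinate descent) and kernel regression
    (epsilon-SVR with an RBF kernel, and a robust Huber-loss kernel regressor fitted
    by Newton's method). For each surgeon and each degree of freedom the best
    selector/regressor pair is chosen by cross-validated correction counts, and the
    resulting plan is evaluated by the number of discrete corrections a surgeon
    would still need to make. A statistical shape model based synthetic-knee
    simulator generates anatomies, rule-based default plans and parameterized
    surgeon-correction behaviour for study-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    kernlab,
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
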