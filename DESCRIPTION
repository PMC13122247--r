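Package: gazemeta
Title: Implicit and Explicit Gaze Perception Analysis with Type-2 ROC
    Metacognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gaze-cueing experiments that measure
    implicit (object detection under task-irrelevant gaze) and explicit
    (deliberate gaze-target judgment) gaze perception together with
    trial-by-trial confidence. Provides trial-table validation for the
    2x2 gaze-validity by body-head-congruency factorial design,
    hierarchical logistic accuracy models and linear confidence models
    with subject-level random effects (via 'lme4' and 'lmerTest'),
    two-stage transfer of per-subject coefficients between tasks,
    criterion-sweep Type-2 ROC metacognitive sensitivity (AUROC2),
    Mahalanobis multivariate outlier screening, Spearman rank
    correlation with autistic-trait (AQ) scores, and a seeded synthetic
    trial generator reproducing the design's statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
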