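Package: icuseq
Title: Tokenized Sequence Models for Multi-Task ICU Acuity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flexible tokenization of irregular electronic health record (EHR)
    event streams and multi-task sequence models for intensive care unit (ICU)
    acuity estimation. Clinical events (vitals, labs, medications, assessment
    scores) are encoded as 12-tuple tokens combining a variable identifier,
    dense-rank position shared across simultaneous measurements, elapsed time,
    and nine value-derived continuous features. A sliding-window/global
    attention transformer encoder with one classification token per outcome
    predicts six readmission and mortality targets simultaneously; gated
    recurrent unit (GRU) and gradient-boosted-tree baselines, a synthetic ICU
    cohort generator with a planted acuity signal, and a split/train/evaluate
    harness with rank-based AUROC and early stopping complete the pipeline.
    All neural models run on a small built-in reverse-mode automatic
    differentiation engine over base R matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
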