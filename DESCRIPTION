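Package: posturekit
Title: Quality Control and Analysis of Continuous Inpatient Posture Telemetry
Version: 0.1.0
Authors@R: person("posturekit", "maintainers", email = "maintainers@posturekit.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for 15-second wearable posture telemetry
    recorded during hospital stays: ingestion of recording and admission
    tables, flagging and exclusion of record-overlap and admission-window
    inconsistency errors, consolidation of raw posture codes into five
    posture groups, majority-vote smoothing of single-timestamp noise,
    per-patient summary statistics of posture duration and transition
    frequency over whole-day, daytime and nighttime windows, and k-means
    subtyping of patients with silhouette-based model selection. Includes a
    synthetic cohort generator with ground-truth error injection so every
    stage is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    igraph,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
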