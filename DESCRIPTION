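Package: timemapr
Title: Evoked-Potential Microstate Analysis of Self-Projection in Time and
    Schizotypal Perceptual Aberration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking schizotypy questionnaire scores (the temporal
    and classical Perceptual Aberration Scales) to behaviour and
    evoked-potential (EP) microstate dynamics in a self-projection-in-time
    task. Implements questionnaire scoring and score-level statistics,
    reaction-time and accuracy aggregation with within-subject ANOVA,
    EP preprocessing (amplitude-based epoch rejection, zero-phase band-pass
    filtering, average referencing), topographic microstate segmentation by
    modified spatial k-means with a cross-validation criterion for model
    order, competitive back-fitting yielding per-map duration and global
    field power, and a distributed linear inverse (local autoregressive
    average prior) on a three-shell spherical head model. A latent-trait
    synthetic-data generator produces questionnaire, behavioural and
    192-channel EP cohorts with planted microstate structure so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
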