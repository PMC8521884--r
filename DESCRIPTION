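Package: dbmarkers
Title: Digital Facial, Vocal and Head-Movement Markers of Depression
    Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes remote digital-phenotyping markers of depression from
    per-frame face-tracking output (OpenFace CSV dialect) and mono audio:
    six facial emotion counts and intensities derived from Facial Action
    Coding System action units, an overall expressivity composite, a voice
    percentage from energy-based speech detection, and head-movement
    kinematics from pose time series.  Measures longitudinal treatment
    response with repeated-measures ANOVA, Mauchly sphericity testing,
    Benjamini-Hochberg false-discovery-rate correction and Tukey pairwise
    contrasts, alongside MADRS-based eligibility, responder and severity
    rules.  Includes an affective stimulus sequencer (valence z-scoring,
    buffered three-class thresholds, no-repeat sequences) and a synthetic
    cohort generator in which a latent severity drives both MADRS
    trajectories and all markers, so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
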