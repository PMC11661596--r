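Package: meaoxia
Title: Multiwell MEA Analysis of Neuronal Network Activity Under Oxygen and
    Temperature Stress
Version: 0.1.0
Authors@R:
    person("MEA", "Analysis Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multiwell micro-electrode array (MEA)
    recordings of human iPSC-derived neuronal networks under combined oxygen
    (normoxia/hypoxia) and temperature (34/37/39 degrees C) regimens: spike
    detection on band-filtered voltage traces, interspike-interval burst
    detection, network-burst detection with channel-concurrency rules, mean
    firing rate / network burst rate / network burst duration time courses
    with per-well baseline normalization, an immunocytochemistry arm that
    classifies live/apoptotic/dead nuclei by marker colocalization and
    quantifies synapsin puncta per 10 micrometres of MAP2-positive neurite,
    and the accompanying statistical protocol (KS normality, ROUT outlier
    flagging, two-way ANOVA with Tukey/Sidak/Dunnett families). A calibrated
    synthetic-data generator emulates condition-dependent activity
    trajectories and microscopy fields so the whole pipeline is testable
    without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
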