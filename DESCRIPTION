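Package: sensproc
Title: Robot-Based Upper-Limb Sensory Processing Assessment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Offline analysis pipeline for a robot-based assessment of
    upper-limb sensory processing, in which participants explore planar
    geometric shapes (passively, driven by the robot, or actively inside a
    haptic corridor), reproduce them with the contralateral arm, and identify
    them among six options. Provides a procedural shape-library generator, a
    synthetic-session simulator for healthy and stroke cohorts, trajectory
    segmentation and time normalization, reproduction-accuracy scoring
    (cross-correlation, dynamic time warping, Procrustes superimposition),
    identification scoring, a one-factor sensory-processing-ability score
    (principal-axis factoring with regression and loading-weighted z scores),
    normative confidence-interval abnormality flags, and robust validation
    statistics (trimmed-mean between-within ANOVAs, Winsorized correlations
    with Fisher-z intervals, Hedges' g, Holm-Bonferroni adjustment, and
    generalized eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
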