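Package: cathtrain
Title: Headless Epiduroscopy Catheter-Insertion Training Simulator
Version: 0.1.0
Authors@R: person("cathtrain", "developers", role = c("aut", "cre"),
    email = "cathtrain@example.org")
Description: A scriptable, headless simulator of serious-game epiduroscopy
    training: cognitive-map scenario graphs over anatomical landmarks,
    tube-shaped virtual fixtures with excursion-based collision scoring,
    catheter tip kinematics with speed control and position correction,
    orthographic fluoroscopy-style projection, synthetic trainee agents
    with learning-curve noise schedules, and mixed-design repeated-measures
    ANOVA with noncentral-F power analysis for evaluating training results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
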