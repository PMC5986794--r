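Package: audiomyo
Title: Simulation and Psychophysical Assessment of Audio-Augmented Myoelectric Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates psychophysical assessment of myoelectric prosthesis
    control strategies. Virtual subjects with tunable internal-model,
    sensory, and controller noise perform target-acquisition, trial-by-trial
    adaptation, and two-interval forced-choice just-noticeable-difference
    experiments under three control strategies: raw regression control (RAW),
    winner-take-all filtered control (FLT), and filtered control with
    audio-augmented feedback (AUG). Includes the surface-EMG signal chain
    (Butterworth filtering, Hudgins time-domain features, support vector
    regression to two wrist degrees of freedom), an adaptive weighted
    up-down staircase, Kalman-style internal-model uncertainty estimation,
    Manhattan path-efficiency and accuracy metrics, and the variance-guided
    statistical comparison procedure (Levene, ANOVA or Welch ANOVA,
    Tukey/Bonferroni or Games-Howell, paired t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
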