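Package: letmyo
Title: Linearly Enhanced Training for Simultaneous and Proportional Myocontrol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning-based intent detection from surface
    electromyography (sEMG) with Linearly Enhanced Training (LET): synthetic
    multi-degree-of-freedom training clusters are built as weighted linear
    combinations of single-DOF activation clusters, with closed-form estimation
    of the combination weights (alpha) from cluster centroids. Includes envelope
    preprocessing and stimulus-driven cluster segmentation, ridge regression and
    random-Fourier-feature kernel ridge regression with a bandwidth grid search
    under repetition-wise cross-validation, target-acquisition metrics for
    online goal-reaching sessions (success rate, task completion time, longest
    stable time), and a seeded multi-subject synthetic sEMG generator with
    known ground-truth combination weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
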