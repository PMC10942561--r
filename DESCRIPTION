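Package: reachkin
Title: Reach-and-Place Movement Kinematics, Group Statistics and
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying goal-directed reach-and-place arm movements
    recorded from a wrist-worn inertial sensor. Simulates cohorts of
    continuous reaching-and-placing trials from superposed minimum-jerk
    submovements with known ground truth, extracts twelve per-trial kinematic
    parameters including three zero-crossing movement-unit statistics, runs a
    group-comparison battery (one-way ANOVA, Welch post-hoc t-tests, Pearson
    correlations with Benjamini-Hochberg false-discovery flags), and
    classifies groups with a batch-normalised multilayer perceptron under
    k-fold cross-validation with permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
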