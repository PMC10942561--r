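# reachkin

Kinematic analysis of continuous goal-directed **reach-and-place** arm
movements recorded from a wrist-worn inertial sensor, aimed at researchers
studying motor differences between healthy adults, typically developing (TD)
children and children with Autism Spectrum Disorder (ASD), and at anyone who
needs a fully testable stand-in for such data.

Because recordings of this task are not publicly deposited, the package
ships a seeded synthetic-cohort generator as a first-class component: trials
are sums of minimum-jerk submovements with known ground truth, so every
downstream stage can be validated against closed-form oracles.

## What it computes

**Twelve per-trial kinematic parameters.** Movement onset is detected when
both the distance from the starting point and the acceleration magnitude
reach 20% of their window maxima. From the movement window the package
computes reaction time, movement time, total distance, average/maximum
velocity, time to peak velocity, average/maximum acceleration, time to peak
acceleration, and three movement-unit statistics: zero crossings of velocity
(Type 1), acceleration (Type 2) and jerk (Type 3) counted per motion axis
with hysteresis and consolidated across axes as
√((n_x² + n_y² + n_z²)/3). More movement units indicate less smooth, more
corrected movement.

**Group statistics.** Per parameter: one-way ANOVA across groups, Welch
post-hoc t-tests for significant parameters, and per-group Pearson
correlations with adaptive-function scores flagged by Benjamini–Hochberg FDR
at q = 0.05. Subject-level aggregation is available to respect trial nesting.

**Classification.** A four-layer multilayer perceptron
(FC–BatchNorm–LeakyReLU ×3, then FC–sigmoid) on nine min-max-normalised
kinematic features, binary cross-entropy, ADAM with the learning rate
dropping from 1e-5 to 1e-6 once training accuracy reaches 95%, 200 epochs,
evaluated by stratified 10-fold cross-validation, plus permutation feature
importance (loss increase when one feature's validation column is shuffled).

The generative model, parameter meanings, defaults and design decisions are
documented in `vignettes/reachkin-methods.Rmd`.

## Worked example

```r
library(reachkin)

co <- simulate_cohort(child_cohort_spec(seed = 42))   # 15 TD + 26 ASD x 6 trials
ft <- extract_cohort_features(co$trials, co$manifest)
head(ft[, c("subject_id", "group", "trial_index", "reaction_time",
            "total_distance", "avg_velocity", "mu_type2_rms")], 4)
#>   subject_id group trial_index reaction_time total_distance avg_velocity mu_type2_rms
#> 1       TD01    TD           1          1.05           2.00        0.266         17.3
#> 2       TD01    TD           2          0.87           2.24        0.287         19.6
#> 3       TD01    TD           3          1.01           2.06        0.281         17.1
#> 4       TD01    TD           4          0.83           2.31        0.305         18.1

bt <- run_battery(ft, aggregate = "subject")
head(bt$anova[order(bt$anova$p), ], 5)
#>         parameter     F df_between df_within        p
#> 10   mu_type1_rms 119.6          1        39 1.91e-13
#> 3  total_distance  98.8          1        39 3.05e-12
#> 11   mu_type2_rms  97.3          1        39 3.78e-12
#> 12   mu_type3_rms  55.2          1        39 5.50e-09
#> 4    avg_velocity  29.0          1        39 3.65e-06

cv <- cross_validate(ft, as.integer(ft$group == "ASD"),
                     classifier_config(seed = 42))
cv$mean_accuracy
#> [1] 0.862
```

Each feature row is one trial (2 m of path over ~8 blocks moved, average
speed ~0.3 m/s, ~18 Type-2 units — a child-scale reach-place trial). The
ANOVA table shows the configured group effects dominating the movement-unit
and distance parameters, and the cross-validated MLP separates the two
synthetic child groups at 86% — a property of the configured effect sizes,
not a claim about real children.

A subcommand CLI wraps the same stages
(`simulate | extract | stats | train | importance | pipeline`):

```sh
Rscript inst/cli/reachkin pipeline --out runs/demo --seed 7
```

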