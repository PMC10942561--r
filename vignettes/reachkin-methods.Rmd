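---
title: "Methods: simulating and analysing reach-and-place kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing reach-and-place kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachkin)
```

# The task and the pipeline

`reachkin` analyses continuous goal-directed reach-and-place arm movements of
the kind recorded by a wrist-worn inertial measurement unit (IMU) while a
child repeatedly picks up blocks and places them into a container. The
pipeline has four stages, each usable on its own:

1. **Simulation** (`simulate_cohort()`): seeded synthetic cohorts of adults,
   typically developing (TD) children and children with Autism Spectrum
   Disorder (ASD), with known ground truth (true movement onsets, true
   submovement counts, configured group effects).
2. **Feature extraction** (`extract_features()`): twelve per-trial kinematic
   parameters, including three zero-crossing movement-unit statistics.
3. **Group statistics** (`run_battery()`): one-way ANOVA per parameter,
   Welch post-hoc t-tests, Pearson correlations with adaptive-function
   scores, Benjamini–Hochberg false-discovery flags.
4. **Classification** (`cross_validate()`, `permutation_importance()`):
   a batch-normalised multilayer perceptron under stratified k-fold
   cross-validation, with permutation feature importance.

Real recordings for this task are not publicly deposited, so the simulator is
a first-class component: every downstream stage is tested against synthetic
cohorts whose generating truth is known exactly.

# The generative model

## Minimum-jerk submovements

Trials are sums of discrete submovements. Each submovement displaces the hand
by a vector $\mathbf{D}$ over a window $[t_0, t_0 + T]$ following the
minimum-jerk profile

$$s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5, \qquad \tau = (t - t_0)/T,$$

the trajectory that minimises integrated squared jerk between two rest
states. This choice is a modelling decision, made because it gives
closed-form position, velocity, acceleration and jerk — so the feature
extractor can be tested against exact oracles: peak speed is $1.875\,D/T$ at
$\tau = 1/2$; the speed profile has mean $D/T$ (peak-to-mean ratio 1.875);
per axis the velocity has no interior zero crossing, the acceleration exactly
one ($\tau = 1/2$) and the jerk exactly two ($\tau = (3 \pm \sqrt{3})/6$).
`render_submovements()` returns these analytic derivatives directly; no
numerical differentiation enters the simulator.

## Trial structure

A trial consists of `blocks_per_trial` (default 4) block moves, each a
primary *reach* (current position to block) and a primary *place* (block to
container). Blocks sit on a 10 cm-radius circle 25 cm in front of the home
position; the container is 25 cm lateral. These geometry constants are fixed
but arbitrary; only their scale matters for the extracted magnitudes.
The first primary starts a Gaussian reaction time after the trigger; primaries
are separated by a 0.2 s dwell emulating grasp and release.

Three mechanisms make movements less smooth, and are the dials that create
group differences:

* **Corrective submovements**: each primary receives a Poisson-distributed
  number of small corrective kernels (amplitude
  `corrective_amplitude_frac` × primary, random direction), starting
  uniformly in the second half of the primary.
* **Overshoot**: with `overshoot_frac > 0` the primary overshoots the target
  and a deterministic pull-back kernel returns to it, adding path length and
  acceleration reversals.
* **Sensor noise**: white Gaussian noise (default sd 0.05 m/s²) is added to
  the *acceleration channel only*. The position channel stays noise-free by
  design so that tests of the differentiation path can isolate numerical
  error from sensor error.

The default sample rate is 100 Hz, a typical value for wrist-worn IMUs;
recordings at or above 20 Hz are accepted.

## Group defaults

The per-group defaults (`default_group_params()`) are *configuration
targets*, not fits to any dataset: they are chosen so that cohort-level
contrasts run in the directions reported for this task — ASD children show
larger total displacement, higher average/maximum velocity and acceleration,
more Type-2 movement units and slower reaction times than TD children, while
adults move farther and faster with far fewer corrective units. Group effects
scale linearly through `effect_scale` (0 gives a null cohort, 2 doubles every
configured deviation from the TD baseline). The control of the two
time-to-peak parameters is deliberately weak: they emerge from where the
fastest submovement happens to fall within the trial rather than from an
explicit dial, so their group contrasts are noisy by construction.

Subjects within a group differ through lognormal multipliers on their speed
scale, corrective rate, amplitude and reaction time, driven by latent
standard-normal tendencies. Two of these latents (speed and movement-unit
tendency) also feed a linear score model producing synthetic
adaptive-function scores in three domains (communication, daily living,
socialization), with group-specific signs mirroring the reported correlation
structure: in TD children daily-living/socialization scores fall with the
movement-unit tendency, in ASD children communication/socialization scores
rise with the speed tendency. Score noise sd defaults to 6 standard-score
points.

The default child cohort is 15 TD + 26 ASD subjects × 6 trials = 246 trials
(63.4% ASD), matching the cohort proportions of the emulated study; the
three-group variant adds 10 adults. A per-trial `dropout_prob` can emulate
excluded trials; it defaults to 0 because no exclusion rule is documented for
the original task.

# Feature extraction

## Signal preparation

When position is available it is low-pass filtered (two-pass, zero-phase
Butterworth; default cutoff 10 Hz, design order 4) and differentiated by
successive central differences to velocity, acceleration and jerk. The
zero-phase filter uses odd-reflection padding and steady-state initial
conditions at both ends, so constant segments pass through exactly and trial
edges carry no transients — an implementation detail that matters because the
onset rule compares signals against their window maxima, which an edge
artefact would corrupt.

When only acceleration is recorded, the filtered acceleration is integrated
(trapezoidal) to velocity and again to position. Because the hand is at rest
at both ends of a trial, any residual endpoint velocity is integration drift
and is removed by subtracting the line through the first and last velocity
samples. On noise-free synthetic trials this path reconstructs velocity to
about 0.1% of its peak at 100 Hz.

## Onset detection and temporal parameters

Movement initiation is the earliest sample in the search window (trigger to
trial end) at which *both* the distance from the starting point and the
acceleration magnitude have reached 20% of their respective window maxima —
read as the later of the two individual threshold crossings. The starting
point is the position at the trigger sample. Reaction time is onset minus
trigger; movement time is trial end minus onset, the end marker being part of
the recording (set by the experimenter in the emulated task; the simulator
places it 0.3 s after the last kernel ends).

Because the threshold is relative to the *maximum* distance reached in the
trial, detected reaction times sit systematically above the generative
reaction-time parameter; group *contrasts* are preserved, which is what the
downstream stages consume.

## Magnitude parameters

Over the movement window: total distance is the summed Euclidean length of
consecutive position increments; average velocity/acceleration are arithmetic
means of the magnitude samples (uniform sampling makes time-weighting
irrelevant); maxima are window maxima; times to peak are measured from onset,
first occurrence on ties.

## Movement units

A movement unit is a zero crossing of a kinematic signal along one motion
axis — a change of direction. Type 1 counts velocity crossings, Type 2
acceleration, Type 3 jerk, per axis (x, y, z). Counting uses hysteresis: with
$M$ the window maximum of $|x|$, a crossing is counted when the signal passes
from $\le -hM$ to $\ge +hM$ or vice versa (default $h = 0.05$), so
noise-driven chatter around zero contributes at most one count per genuine
excursion. Setting $h = 0$ recovers the literal zero-crossing definition used
in the oracle tests. Per-axis counts are consolidated as
$\sqrt{(n_x^2 + n_y^2 + n_z^2)/3}$; the reading of "root mean square" as a
mean over the three axes is configurable (`rms_divisor = "sum"` gives the
root-sum-square instead, since the phrase is ambiguous).

Units are SI throughout; the coordinate frame is the recording's own and no
gravity compensation is applied (synthetic accelerations exclude gravity;
gravity removal for real IMU data is out of scope).

# Group statistics

Per parameter, a classic one-way fixed-effects ANOVA compares the groups
present; parameters reaching $p < 0.05$ get pairwise post-hoc t-tests. The
post-hoc flavour is Welch's unequal-variance t, chosen because the default
group sizes differ (15 vs 26). Pearson correlations relate each parameter to
each score domain within each child group, with Benjamini–Hochberg flags at
$q = 0.05$ computed over the whole correlation table.

Trials are nested within subjects, and the subject-level lognormal
multipliers make within-subject trials correlated. Trial-level ANOVA p-values
are therefore anticonservative; `run_battery(aggregate = "subject")` first
averages each parameter within subject, restoring independent units (the
calibration tests show a ~5% false-positive rate on null cohorts at the
subject level). The trial-level mode remains the default output because the
emulated protocol analysed trial-level samples; the choice is explicit in
every result.

# Classification

## Architecture and training

The classifier is a four-layer fully connected network:
FC(9→64) – BatchNorm – LeakyReLU – FC(64→32) – BatchNorm – LeakyReLU –
FC(32→16) – BatchNorm – LeakyReLU – FC(16→1) – sigmoid, trained with binary
cross-entropy and ADAM (moments 0.9/0.999) for exactly 200 epochs. The
learning rate starts at 1e-5 and drops permanently to 1e-6 at the end of the
first epoch whose training accuracy reaches 95%. The nine default input
features are the parameters that discriminate the child groups (all magnitude
and temporal parameters plus Type-2 movement units); inputs are min-max
normalised.

The hidden widths (64, 32, 16), the loss, leaky slope 0.01, batch-norm
placement and the batch size are design choices, all configurable. Two of
them deserve comment:

* **Batch size 16.** With the learning-rate schedule fixed at 1e-5, total
  parameter movement is bounded by (steps × learning rate), so small batches
  provide the optimisation budget; 16 gives roughly 3,000 ADAM steps over the
  default cohort. Full-batch training also works on well-separated data but
  with less headroom, and batch statistics on singleton batches would
  degenerate, so trailing singletons are merged into the previous batch.
* **Near-zero output-layer initialisation.** Hidden layers use He-style
  initialisation, but the output layer starts at sd 1e-3. The initial logits
  are then uninformative and the *trained* gradient direction — not the luck
  of the random readout — determines the decision sign. This is what lets a
  budget of a few thousand small steps reach high thresholded accuracy: the
  decision rule needs the correct logit sign, not large logits.

All randomness (weights, shuffles, folds, permutations) is drawn from R's
seeded RNG, so a fixed (data, configuration, seed) triple reproduces results
bit-identically.

## Cross-validation and importance

`cross_validate()` builds stratified folds (10 by default) by dealing
shuffled class members round-robin; with a `grouping` argument, folds never
split a subject. Each fold's model trains on the remainder, uses the held-out
fold as its validation set for loss tracking, and is scored on it at the 0.5
sigmoid threshold. The default normalisation scope is `whole_dataset`,
mirroring the emulated protocol's normalisation over the entire dataset; it
leaks range information across folds, so `per_fold_train` is offered as a
first-class alternative and the leakage audit in the test suite verifies that
the per-fold ranges never see held-out rows.

Permutation feature importance shuffles one feature column of the validation
table at a time, re-evaluates the model at its best-validation-loss
parameters and reports the mean loss increase over 10 seeded shuffles
(averaging stabilises the single-shuffle protocol). The identity permutation
yields exactly zero by construction.

# What the synthetic cohorts do and do not show

The simulator emulates: the task's trial structure, smooth submovement
kinematics with corrective activity, group effect *directions*, trial-level
class imbalance (63.4% ASD), subject-level heterogeneity, and score-kinematic
correlations with the reported sign structure. It does not emulate: real
IMU noise spectra or gravity/orientation artefacts, the partner's mirrored
movements, grasp mechanics, fatigue or learning across trials, or the actual
effect magnitudes of the real cohort. Consequently, passing tests demonstrate
that the pipeline recovers what the generator put in — they do not certify
classification accuracy on real recordings, and the package deliberately does
not claim to reproduce any real-data accuracy figure.

# Numerical choices and degenerate inputs

* Tolerances: analytic oracle tests allow 1–2% for quantities passing through
  the 10 Hz filter and central differences; statistics wrappers match
  brute-force oracles to 1e-10 relative.
* Recordings shorter than 10 samples, windows with fewer than 2 samples,
  flat signals in the onset window, zero-variance correlation inputs and
  all-constant ANOVA groups raise typed errors naming the offending trial.
* Constant features min-max normalise to 0.5 with a warning flag.
* Ties in argmax (peak times) take the first occurrence; BH flags are
  monotone in p by construction.
* CSV output rounds to 6 significant digits; equality of repeated pipeline
  runs is byte-level, numeric comparisons in tests use tolerances.

# Problem sizes used in the shipped checks

The test suite exercises: 1,000-case random-vector equivalence for the
zero-crossing counter; 100 seeded cohorts for effect-direction recovery and
200 for null calibration (each 41 subjects × 6 trials at 100 Hz); 10-seed
batteries for chance-level classifier calibration and importance ranking.
These sizes give Monte-Carlo error comfortably below the asserted margins
while keeping a full run of the suite in the ten-minute range on one core.

# Known limitations

* The onset rule's dependence on window maxima couples reaction time to trial
  amplitude; alternative absolute-threshold rules are not implemented.
* Per-reach segmentation within a trial is out of scope — all parameters are
  per-trial, matching the emulated protocol.
* The acceleration-only path assumes rest at both trial ends for drift
  removal; trials truncated mid-movement would bias it.
* The MLP protocol fixes epochs and learning rates rather than early
  stopping; with very small folds the best-validation-loss epoch can sit at
  a noisy minimum.
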