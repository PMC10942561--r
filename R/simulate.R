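#' Generative parameters for one participant group
#'
#' Describes how reach-and-place trials are generated for a group: reaction
#' time, primary submovement duration and amplitude, the rate and relative
#' amplitude of corrective submovements, target overshoot, a peak-speed
#' multiplier and the accelerometer noise level.
#'
#' @param group_label one of `"ADULT"`, `"TD"`, `"ASD"`.
#' @param reaction_time_mean,reaction_time_sd seconds.
#' @param primary_duration_mean,primary_duration_sd seconds; duration of a
#'   primary (reach or place) submovement.
#' @param reach_amplitude_mean,reach_amplitude_sd metres.
#' @param corrective_rate expected corrective submovements per primary
#'   (Poisson mean).
#' @param corrective_amplitude_frac corrective amplitude as a fraction of the
#'   primary amplitude, in `[0, 1]`.
#' @param overshoot_frac fractional target overshoot in `[0, 1)`; an overshoot
#'   adds a deterministic pull-back submovement.
#' @param peak_speed_scale dimensionless; divides the drawn primary duration so
#'   peak speed scales up without changing amplitude.
#' @param noise_sd_acc white sensor noise added to the acceleration channel
#'   only, m/s^2.
#' @return An object of class `group_params`.
#' @export
group_params <- function(group_label,
                         reaction_time_mean, reaction_time_sd,
                         primary_duration_mean, primary_duration_sd,
                         reach_amplitude_mean, reach_amplitude_sd,
                         corrective_rate, corrective_amplitude_frac,
                         overshoot_frac, peak_speed_scale, noise_sd_acc) {
  group_label <- match.arg(group_label, c("ADULT", "TD", "ASD"))
  sds <- c(reaction_time_sd, primary_duration_sd, reach_amplitude_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (corrective_rate < 0) stop("corrective_rate must be >= 0", call. = FALSE)
  if (corrective_amplitude_frac < 0 || corrective_amplitude_frac > 1)
    stop("corrective_amplitude_frac must lie in [0, 1]", call. = FALSE)
  if (overshoot_frac < 0 || overshoot_frac >= 1)
    stop("overshoot_frac must lie in [0, 1)", call. = FALSE)
  if (peak_speed_scale <= 0) stop("peak_speed_scale must be > 0", call. = FALSE)
  if (noise_sd_acc < 0) stop("noise_sd_acc must be >= 0", call. = FALSE)
  structure(list(group_label = group_label,
                 reaction_time_mean = reaction_time_mean,
                 reaction_time_sd = reaction_time_sd,
                 primary_duration_mean = primary_duration_mean,
                 primary_duration_sd = primary_duration_sd,
                 reach_amplitude_mean = reach_amplitude_mean,
                 reach_amplitude_sd = reach_amplitude_sd,
                 corrective_rate = corrective_rate,
                 corrective_amplitude_frac = corrective_amplitude_frac,
                 overshoot_frac = overshoot_frac,
                 peak_speed_scale = peak_speed_scale,
                 noise_sd_acc = noise_sd_acc),
            class = "group_params")
}

#' Default group parameters
#'
#' Built-in generative defaults for healthy adults, typically developing (TD)
#' children and children with ASD. They are configuration targets chosen so
#' that cohort-level contrasts run in the directions reported for this task
#' (ASD children: larger displacement, higher average/maximum velocity and
#' acceleration, more Type-2 movement units, slower reaction times; adults:
#' fewer corrective units and faster reaction times than TD children). They
#' are not estimates fitted to any real dataset.
#'
#' @param group `"ADULT"`, `"TD"` or `"ASD"`.
#' @param effect_scale multiplier on the ASD/ADULT deviations from the TD
#'   baseline; `effect_scale = 2` doubles every configured group effect,
#'   `effect_scale = 0` yields TD-identical parameters (a null group).
#' @return A [group_params] object.
#' @export
default_group_params <- function(group = c("TD", "ASD", "ADULT"),
                                 effect_scale = 1) {
  group <- match.arg(group)
  td <- list(reaction_time_mean = 0.55, reaction_time_sd = 0.08,
             primary_duration_mean = 0.72, primary_duration_sd = 0.07,
             reach_amplitude_mean = 0.26, reach_amplitude_sd = 0.02,
             corrective_rate = 1.0, corrective_amplitude_frac = 0.15,
             overshoot_frac = 0.02, peak_speed_scale = 1.0,
             noise_sd_acc = 0.05)
  dev <- switch(group,
    TD = td,
    ASD = list(reaction_time_mean = 0.64, reaction_time_sd = 0.10,
               primary_duration_mean = 0.80, primary_duration_sd = 0.08,
               reach_amplitude_mean = 0.29, reach_amplitude_sd = 0.02,
               corrective_rate = 2.2, corrective_amplitude_frac = 0.18,
               overshoot_frac = 0.10, peak_speed_scale = 1.05,
               noise_sd_acc = 0.05),
    ADULT = list(reaction_time_mean = 0.38, reaction_time_sd = 0.06,
                 primary_duration_mean = 0.88, primary_duration_sd = 0.08,
                 reach_amplitude_mean = 0.36, reach_amplitude_sd = 0.02,
                 corrective_rate = 0.3, corrective_amplitude_frac = 0.12,
                 overshoot_frac = 0.0, peak_speed_scale = 1.12,
                 noise_sd_acc = 0.05))
  p <- mapply(function(base, d) base + effect_scale * (d - base), td, dev,
              SIMPLIFY = FALSE)
  # keep scaled parameters inside their legal ranges
  p$corrective_rate <- max(p$corrective_rate, 0)
  p$overshoot_frac <- min(max(p$overshoot_frac, 0), 0.95)
  p$corrective_amplitude_frac <- min(max(p$corrective_amplitude_frac, 0), 1)
  p$peak_speed_scale <- max(p$peak_speed_scale, 0.1)
  for (f in c("reaction_time_sd", "primary_duration_sd", "reach_amplitude_sd",
              "noise_sd_acc"))
    p[[f]] <- max(p[[f]], 0)
  do.call(group_params, c(list(group_label = group), p))
}

# Fixed task geometry: home position at the origin, blocks on a circle in the
# transverse plane in front of the child, container placed laterally.
task_geometry <- function(blocks_per_trial) {
  ang <- seq(0, 2 * pi, length.out = blocks_per_trial + 1L)[seq_len(blocks_per_trial)]
  list(home = c(0, 0, 0),
       blocks = cbind(0.10 * cos(ang), 0.25 + 0.10 * sin(ang), 0.05),
       container = c(0.25, 0.25, 0),
       dwell = 0.2)
}

#' Trial recording container
#'
#' One trial's time-stamped 3-axis wrist trajectory with trial markers and
#' subject metadata. Validates the container invariants: uniform strictly
#' increasing time, aligned channel lengths, markers inside the recording.
#'
#' @param subject_id character scalar.
#' @param group_label `"ADULT"`, `"TD"` or `"ASD"`.
#' @param trial_index positive integer.
#' @param sample_rate Hz.
#' @param t time vector, seconds.
#' @param pos,acc `T x 3` matrices (m, m/s^2); either may be `NULL` but not both.
#' @param trigger_time,end_time trial start cue and experimenter-marked end,
#'   seconds.
#' @param ground_truth optional list with the true onset time and the true
#'   per-primary submovement counts (populated by the simulator).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, group_label, trial_index, sample_rate,
                            t, pos = NULL, acc = NULL,
                            trigger_time, end_time, ground_truth = NULL) {
  group_label <- match.arg(group_label, c("ADULT", "TD", "ASD"))
  if (is.null(pos) && is.null(acc))
    stop("at least one of pos/acc must be present", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-9)
    stop("t must be strictly increasing and uniform", call. = FALSE)
  n <- length(t)
  for (m in list(pos = pos, acc = acc)) {
    if (!is.null(m) && (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L))
      stop("pos/acc must be T x 3 matrices aligned with t", call. = FALSE)
  }
  if (trigger_time > end_time)
    stop("trigger_time must not exceed end_time", call. = FALSE)
  if (trigger_time < t[1L] - 1e-9 || end_time > t[n] + 1e-9)
    stop("trial markers must lie within the recording", call. = FALSE)
  structure(list(subject_id = subject_id, group_label = group_label,
                 trial_index = as.integer(trial_index),
                 sample_rate = sample_rate, t = t, pos = pos, acc = acc,
                 trigger_time = trigger_time, end_time = end_time,
                 ground_truth = ground_truth),
            class = "trial_recording")
}

# Draw the submovement plan for one trial using the current RNG state.
# Returns the kernel list plus ground truth, without rendering, so large
# Monte-Carlo checks of submovement counts stay cheap.
plan_trial <- function(params, blocks_per_trial = 4L, trigger_time = 0.5) {
  stopifnot(inherits(params, "group_params"), blocks_per_trial >= 1L)
  geom <- task_geometry(blocks_per_trial)
  rt <- max(0.05, stats::rnorm(1L, params$reaction_time_mean,
                               params$reaction_time_sd))
  cur_pos <- geom$home
  cur_time <- trigger_time + rt
  kernels <- list()
  counts <- integer(0)
  targets <- vector("list", 2L * blocks_per_trial)
  for (b in seq_len(blocks_per_trial)) {
    targets[[2L * b - 1L]] <- geom$blocks[b, ]
    targets[[2L * b]] <- geom$container
  }
  for (tg in targets) {
    dur <- max(0.2, stats::rnorm(1L, params$primary_duration_mean,
                                 params$primary_duration_sd)) /
      params$peak_speed_scale
    amp <- max(0.05, stats::rnorm(1L, params$reach_amplitude_mean,
                                  params$reach_amplitude_sd))
    dir <- tg - cur_pos
    dirn <- sqrt(sum(dir^2))
    u <- if (dirn > 1e-9) dir / dirn else c(1, 0, 0)
    n_this <- 1L
    primary_disp <- u * amp * (1 + params$overshoot_frac)
    kernels[[length(kernels) + 1L]] <-
      submovement_kernel(cur_time, dur, primary_disp)
    last_end <- cur_time + dur
    if (params$overshoot_frac > 0) {
      # deterministic pull-back onto the nominal endpoint
      kb <- submovement_kernel(cur_time + 0.7 * dur, 0.4 * dur,
                               -u * amp * params$overshoot_frac)
      kernels[[length(kernels) + 1L]] <- kb
      last_end <- max(last_end, kb$start_time + kb$duration)
      n_this <- n_this + 1L
    }
    n_corr <- stats::rpois(1L, params$corrective_rate)
    if (n_corr > 0L) {
      for (j in seq_len(n_corr)) {
        st <- cur_time + stats::runif(1L, 0.5, 1.0) * dur
        cd <- stats::runif(1L, 0.25, 0.45) * dur
        v <- stats::rnorm(3L)
        v <- v / sqrt(sum(v^2))
        kc <- submovement_kernel(st, cd,
                                 v * params$corrective_amplitude_frac * amp)
        kernels[[length(kernels) + 1L]] <- kc
        last_end <- max(last_end, st + cd)
        n_this <- n_this + 1L
      }
    }
    counts <- c(counts, n_this)
    # hand position actually reached (sum of all displacements this primary)
    cur_pos <- cur_pos + Reduce(`+`, lapply(
      kernels[(length(kernels) - n_this + 1L):length(kernels)],
      `[[`, "displacement"))
    cur_time <- last_end + geom$dwell
  }
  list(kernels = kernels,
       onset_time = kernels[[1L]]$start_time,
       submovement_counts = counts,
       end_time = max(vapply(kernels, function(k) k$start_time + k$duration,
                             numeric(1L))) + 0.3)
}

#' Simulate one reach-and-place trial
#'
#' Generates a continuous multi-block trial: per block a primary reach
#' (home/container to block) and a primary place (block to container), each
#' with Poisson-distributed corrective submovements started uniformly in the
#' second half of the primary, and an overshoot pull-back when
#' `overshoot_frac > 0`. The first primary starts `reaction_time` after the
#' trigger. White Gaussian noise is added to the acceleration channel only;
#' the position channel stays noise-free.
#'
#' @param params a [group_params] object.
#' @param blocks_per_trial number of blocks to move.
#' @param sample_rate Hz (>= 20).
#' @param trigger_time trial start cue, seconds.
#' @param seed optional integer; when given, seeds the RNG so the trial is
#'   reproducible. When `NULL` the current RNG state is used.
#' @param subject_id,trial_index metadata carried into the recording.
#' @return A [trial_recording] with `ground_truth` populated (true onset time
#'   and per-primary submovement counts).
#' @export
simulate_trial <- function(params, blocks_per_trial = 4L, sample_rate = 100,
                           trigger_time = 0.5, seed = NULL,
                           subject_id = "S1", trial_index = 1L) {
  if (sample_rate < 20) stop("sample_rate must be >= 20 Hz", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  plan <- plan_trial(params, blocks_per_trial, trigger_time)
  t <- seq(0, ceiling(plan$end_time * sample_rate) / sample_rate,
           by = 1 / sample_rate)
  tr <- render_submovements(plan$kernels, t)
  acc <- tr$acc
  if (params$noise_sd_acc > 0)
    acc <- acc + matrix(stats::rnorm(length(t) * 3L, 0, params$noise_sd_acc),
                        ncol = 3L)
  trial_recording(subject_id = subject_id, group_label = params$group_label,
                  trial_index = trial_index, sample_rate = sample_rate,
                  t = t, pos = tr$pos, acc = acc,
                  trigger_time = trigger_time,
                  end_time = min(plan$end_time, t[length(t)]),
                  ground_truth = list(onset_time = plan$onset_time,
                                      submovement_counts = plan$submovement_counts))
}

#' Default adaptive-function score model
#'
#' Linear links from per-subject latent kinematic tendencies (a velocity
#' tendency and a movement-unit tendency, both standard normal) to synthetic
#' adaptive-function scores in three domains (communication, daily living,
#' socialization). Default signs follow the reported correlation structure:
#' TD children's daily-living/socialization scores fall with movement-unit
#' tendency and rise with velocity tendency; ASD children's communication and
#' socialization scores rise with velocity tendency.
#'
#' @param noise_sd score noise standard deviation.
#' @return A list with per-group base levels and link coefficient matrices
#'   (rows: domains com/dl/soc, columns: latents vel/mu).
#' @export
default_score_model <- function(noise_sd = 6) {
  list(base = list(TD = c(com = 103, dl = 101, soc = 100),
                   ASD = c(com = 83, dl = 80, soc = 73)),
       coef = list(
         TD = rbind(com = c(vel = 0, mu = 0),
                    dl = c(vel = 4, mu = -8),
                    soc = c(vel = 6, mu = -6)),
         ASD = rbind(com = c(vel = 5, mu = 0),
                     dl = c(vel = 0, mu = 0),
                     soc = c(vel = 7, mu = 0))),
       noise_sd = noise_sd)
}

#' Cohort specification
#'
#' @param groups list of `list(params = group_params, n_subjects = n)` entries.
#' @param trials_per_subject trials per subject (default 6, the task's trial
#'   count).
#' @param blocks_per_trial blocks moved per trial.
#' @param sample_rate Hz (>= 20).
#' @param seed integer; the same (spec, seed) always reproduces the cohort
#'   bit-identically.
#' @param score_model see [default_score_model()]; adult subjects receive `NA`
#'   scores.
#' @param dropout_prob per-trial exclusion probability emulating discarded
#'   trials (default 0).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, trials_per_subject = 6L, blocks_per_trial = 4L,
                        sample_rate = 100, seed = 1L,
                        score_model = default_score_model(),
                        dropout_prob = 0) {
  if (length(groups) == 0L) stop("at least one group is required", call. = FALSE)
  for (g in groups) {
    if (!inherits(g$params, "group_params") || g$n_subjects < 1L)
      stop("each group needs group_params and n_subjects >= 1", call. = FALSE)
  }
  if (trials_per_subject < 1L) stop("trials_per_subject must be >= 1", call. = FALSE)
  if (blocks_per_trial < 1L) stop("blocks_per_trial must be >= 1", call. = FALSE)
  if (sample_rate < 20) stop("sample_rate must be >= 20 Hz", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  structure(list(groups = groups, trials_per_subject = as.integer(trials_per_subject),
                 blocks_per_trial = as.integer(blocks_per_trial),
                 sample_rate = sample_rate, seed = as.integer(seed),
                 score_model = score_model, dropout_prob = dropout_prob),
            class = "cohort_spec")
}

#' Default child cohort specification
#'
#' 15 TD and 26 ASD children, 6 trials each (246 trials, 63.4% ASD), matching
#' the cohort proportions of the task this package emulates.
#'
#' @param n_td,n_asd subjects per group.
#' @param effect_scale passed to [default_group_params()] for the ASD group;
#'   `0` yields a null cohort whose two groups share TD generative parameters.
#' @param seed,trials_per_subject,blocks_per_trial,dropout_prob see [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
child_cohort_spec <- function(n_td = 15L, n_asd = 26L, effect_scale = 1,
                              seed = 1L, trials_per_subject = 6L,
                              blocks_per_trial = 4L, dropout_prob = 0) {
  cohort_spec(groups = list(
                list(params = default_group_params("TD"), n_subjects = n_td),
                list(params = default_group_params("ASD", effect_scale),
                     n_subjects = n_asd)),
              trials_per_subject = trials_per_subject,
              blocks_per_trial = blocks_per_trial, seed = seed,
              dropout_prob = dropout_prob)
}

#' Default three-group cohort specification
#'
#' Adds a healthy-adult comparison group to [child_cohort_spec()].
#'
#' @param n_adult,n_td,n_asd subjects per group.
#' @param effect_scale multiplier on the configured ADULT and ASD deviations
#'   from the TD baseline.
#' @param seed,trials_per_subject,blocks_per_trial see [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
three_group_cohort_spec <- function(n_adult = 10L, n_td = 15L, n_asd = 26L,
                                    effect_scale = 1, seed = 1L,
                                    trials_per_subject = 6L,
                                    blocks_per_trial = 4L) {
  cohort_spec(groups = list(
                list(params = default_group_params("ADULT", effect_scale),
                     n_subjects = n_adult),
                list(params = default_group_params("TD"), n_subjects = n_td),
                list(params = default_group_params("ASD", effect_scale),
                     n_subjects = n_asd)),
              trials_per_subject = trials_per_subject,
              blocks_per_trial = blocks_per_trial, seed = seed)
}

# Per-subject parameter jitter: latent tendencies (standard normal) modulate
# the group parameters multiplicatively so subjects differ but stay in-group.
subject_params <- function(params, z) {
  p <- unclass(params)
  p$peak_speed_scale <- p$peak_speed_scale * exp(0.06 * z[["vel"]])
  p$corrective_rate <- p$corrective_rate * exp(0.30 * z[["mu"]])
  p$reach_amplitude_mean <- p$reach_amplitude_mean * exp(0.05 * z[["amp"]])
  p$reaction_time_mean <- p$reaction_time_mean * exp(0.10 * z[["rt"]])
  do.call(group_params, p)
}

#' Simulate a full cohort
#'
#' Draws per-subject latent tendencies, simulates `trials_per_subject` trials
#' per subject and builds a manifest with synthetic adaptive-function scores
#' generated by the score model's linear link on the subject latents.
#'
#' @param spec a [cohort_spec].
#' @return A list with `trials` (list of [trial_recording]), `manifest`
#'   (data.frame keyed by subject and trial, with trial markers and scores)
#'   and `subjects` (per-subject latents and scores).
#' @examples
#' co <- simulate_cohort(child_cohort_spec(n_td = 2, n_asd = 2,
#'                                         trials_per_subject = 2))
#' nrow(co$manifest)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  trials <- list()
  manifest <- list()
  subjects <- list()
  sidx <- 0L
  for (g in spec$groups) {
    glab <- g$params$group_label
    for (s in seq_len(g$n_subjects)) {
      sidx <- sidx + 1L
      sid <- sprintf("%s%02d", glab, s)
      z <- c(vel = stats::rnorm(1L), mu = stats::rnorm(1L),
             amp = stats::rnorm(1L), rt = stats::rnorm(1L))
      sp <- subject_params(g$params, z)
      scores <- c(vabs_com = NA_real_, vabs_dl = NA_real_, vabs_soc = NA_real_)
      sm <- spec$score_model
      if (glab %in% names(sm$coef)) {
        mu <- sm$base[[glab]] + as.numeric(sm$coef[[glab]] %*% z[c("vel", "mu")])
        scores <- stats::setNames(mu + stats::rnorm(3L, 0, sm$noise_sd),
                                  c("vabs_com", "vabs_dl", "vabs_soc"))
      }
      subjects[[sidx]] <- data.frame(subject_id = sid, group = glab,
                                     z_vel = z[["vel"]], z_mu = z[["mu"]],
                                     t(scores))
      for (tr in seq_len(spec$trials_per_subject)) {
        if (spec$dropout_prob > 0 && stats::runif(1L) < spec$dropout_prob) next
        rec <- simulate_trial(sp, spec$blocks_per_trial, spec$sample_rate,
                              trigger_time = 0.5, seed = NULL,
                              subject_id = sid, trial_index = tr)
        trials[[length(trials) + 1L]] <- rec
        manifest[[length(manifest) + 1L]] <-
          structure(list(subject_id = sid, group = glab, trial_index = tr,
                         file = NA_character_,
                         trigger_time = rec$trigger_time,
                         end_time = rec$end_time,
                         vabs_com = scores[["vabs_com"]],
                         vabs_dl = scores[["vabs_dl"]],
                         vabs_soc = scores[["vabs_soc"]]),
                    class = "data.frame", row.names = c(NA, -1L))
      }
    }
  }
  list(trials = trials,
       manifest = do.call(rbind, manifest),
       subjects = do.call(rbind, subjects))
}
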