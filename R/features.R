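#' Count zero crossings of a signal, with optional hysteresis
#'
#' With hysteresis, the signal is quantised against the band
#' `[-h*M, +h*M]` (with `M = max(|x|)`): a crossing is counted each time the
#' signal passes from at or below the lower bound to at or above the upper
#' bound, or vice versa, so a signal lingering around zero contributes at
#' most one count per excursion pair. With `hysteresis_frac = 0` this reduces
#' to the number of strict sign changes scanning left to right, ignoring
#' exact zeros.
#'
#' @param x numeric vector (finite).
#' @param hysteresis_frac band half-width as a fraction of `max(|x|)`, in
#'   `[0, 1)`.
#' @return Integer count (0 for empty or all-zero input).
#' @examples
#' count_sign_crossings(c(1, -1, 1, -1))  # 3
#' @export
count_sign_crossings <- function(x, hysteresis_frac = 0) {
  if (hysteresis_frac < 0 || hysteresis_frac >= 1)
    stop("hysteresis_frac must lie in [0, 1)", call. = FALSE)
  if (length(x) == 0L) return(0L)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  m <- max(abs(x))
  if (m == 0) return(0L)
  thr <- hysteresis_frac * m
  lev <- integer(length(x))
  if (hysteresis_frac > 0) {
    # band edges belong to the saturated states
    lev[x >= thr] <- 1L
    lev[x <= -thr] <- -1L
  } else {
    lev[x > 0] <- 1L
    lev[x < 0] <- -1L
  }
  lev <- lev[lev != 0L]
  if (length(lev) < 2L) return(0L)
  sum(diff(lev) != 0L)
}

#' Movement-unit counting configuration
#'
#' @param hysteresis_frac passed to [count_sign_crossings()]; the default 0.05
#'   suppresses noise-driven crossings, 0 recovers the literal zero-crossing
#'   definition.
#' @param rms_divisor `"mean"` consolidates per-axis counts as
#'   \eqn{\sqrt{(n_x^2+n_y^2+n_z^2)/3}}; `"sum"` uses the root-sum-square.
#' @return An object of class `movement_unit_config`.
#' @export
movement_unit_config <- function(hysteresis_frac = 0.05,
                                 rms_divisor = c("mean", "sum")) {
  rms_divisor <- match.arg(rms_divisor)
  if (hysteresis_frac < 0 || hysteresis_frac >= 1)
    stop("hysteresis_frac must lie in [0, 1)", call. = FALSE)
  structure(list(hysteresis_frac = hysteresis_frac, rms_divisor = rms_divisor),
            class = "movement_unit_config")
}

#' Movement-unit statistics (Types 1-3)
#'
#' A movement unit is a zero crossing of a kinematic signal along one motion
#' axis — a change of direction. Type 1 counts velocity crossings, Type 2
#' acceleration crossings, Type 3 jerk crossings, each per axis (x, y, z),
#' consolidated across axes by the root mean square of the three counts.
#'
#' @param vel,acc,jerk in-window `T x 3` component matrices.
#' @param cfg a [movement_unit_config].
#' @return A list with `mu_type1_rms`, `mu_type2_rms`, `mu_type3_rms`;
#'   the per-axis count matrix is attached as attribute `"counts"`.
#' @export
movement_units <- function(vel, acc, jerk, cfg = movement_unit_config()) {
  stopifnot(nrow(vel) == nrow(acc), nrow(acc) == nrow(jerk))
  counts <- vapply(list(type1 = vel, type2 = acc, type3 = jerk),
                   function(m) vapply(seq_len(3L), function(j)
                     count_sign_crossings(m[, j], cfg$hysteresis_frac),
                     integer(1L)),
                   integer(3L))
  div <- if (cfg$rms_divisor == "mean") 3 else 1
  rms <- sqrt(colSums(counts^2) / div)
  structure(list(mu_type1_rms = rms[["type1"]],
                 mu_type2_rms = rms[["type2"]],
                 mu_type3_rms = rms[["type3"]]),
            counts = counts)
}

#' Magnitude and path parameters over the movement window
#'
#' @param vel_mag,acc_mag velocity/acceleration magnitude vectors aligned
#'   with `t`.
#' @param pos `T x 3` position matrix.
#' @param t time vector, seconds.
#' @param onset,end movement window bounds, seconds.
#' @return A list with `total_distance` (path length, m), `avg_velocity`,
#'   `max_velocity` (m/s), `time_to_peak_velocity` (s from onset),
#'   `avg_acceleration`, `max_acceleration` (m/s^2) and
#'   `time_to_peak_acceleration` (s from onset). Averages are means of the
#'   magnitude samples in-window; peak times use the first maximum on ties.
#' @export
compute_magnitude_params <- function(vel_mag, acc_mag, pos, t, onset, end) {
  idx <- which(t >= onset - 1e-12 & t <= end + 1e-12)
  if (length(idx) < 2L)
    stop("movement window must contain at least two samples", call. = FALSE)
  p <- pos[idx, , drop = FALSE]
  step <- sqrt(rowSums(diff(p)^2))
  vm <- vel_mag[idx]
  am <- acc_mag[idx]
  tw <- t[idx]
  list(total_distance = sum(step),
       avg_velocity = mean(vm),
       max_velocity = max(vm),
       time_to_peak_velocity = tw[which.max(vm)] - onset,
       avg_acceleration = mean(am),
       max_acceleration = max(am),
       time_to_peak_acceleration = tw[which.max(am)] - onset)
}

#' Extract the twelve kinematic parameters from one trial
#'
#' Runs the full per-trial chain: signal preparation, onset detection by the
#' 20% dual-threshold rule, then temporal, magnitude and movement-unit
#' parameters over the movement window `[onset, end_time]`. Relative distance
#' for onset detection is measured from the position at the trigger sample.
#'
#' @param rec a [trial_recording].
#' @param prep_cfg a [signal_prep_config].
#' @param onset_cfg an [onset_config].
#' @param mu_cfg a [movement_unit_config].
#' @param use_channel passed to [prepare_signals()].
#' @return A one-row data.frame: `subject_id`, `group`, `trial_index`, then
#'   `reaction_time`, `movement_time`, `total_distance`, `avg_velocity`,
#'   `max_velocity`, `time_to_peak_velocity`, `avg_acceleration`,
#'   `max_acceleration`, `time_to_peak_acceleration`, `mu_type1_rms`,
#'   `mu_type2_rms`, `mu_type3_rms`.
#' @export
extract_features <- function(rec, prep_cfg = signal_prep_config(),
                             onset_cfg = onset_config(),
                             mu_cfg = movement_unit_config(),
                             use_channel = c("auto", "acc")) {
  stopifnot(inherits(rec, "trial_recording"))
  use_channel <- match.arg(use_channel)
  annotate <- function(e) {
    stop(sprintf("trial (%s, %d): %s", rec$subject_id, rec$trial_index,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    sig <- prepare_signals(rec, prep_cfg, use_channel)
    ref_idx <- which.min(abs(sig$t - rec$trigger_time))
    pos_rel <- rownorm(sig$pos - matrix(sig$pos[ref_idx, ], nrow(sig$pos), 3L,
                                        byrow = TRUE))
    onset <- detect_onset(pos_rel, sig$acc_mag, sig$t, onset_cfg,
                          rec$trigger_time, rec$end_time)
    tp <- compute_temporal_params(onset, rec$trigger_time, rec$end_time)
    mg <- compute_magnitude_params(sig$vel_mag, sig$acc_mag, sig$pos, sig$t,
                                   onset, rec$end_time)
    widx <- which(sig$t >= onset - 1e-12 & sig$t <= rec$end_time + 1e-12)
    mu <- movement_units(sig$vel[widx, , drop = FALSE],
                         sig$acc[widx, , drop = FALSE],
                         sig$jerk[widx, , drop = FALSE], mu_cfg)
    structure(list(subject_id = rec$subject_id, group = rec$group_label,
                   trial_index = rec$trial_index,
                   reaction_time = tp$reaction_time,
                   movement_time = tp$movement_time,
                   total_distance = mg$total_distance,
                   avg_velocity = mg$avg_velocity,
                   max_velocity = mg$max_velocity,
                   time_to_peak_velocity = mg$time_to_peak_velocity,
                   avg_acceleration = mg$avg_acceleration,
                   max_acceleration = mg$max_acceleration,
                   time_to_peak_acceleration = mg$time_to_peak_acceleration,
                   mu_type1_rms = mu$mu_type1_rms,
                   mu_type2_rms = mu$mu_type2_rms,
                   mu_type3_rms = mu$mu_type3_rms),
              class = "data.frame", row.names = c(NA, -1L))
  }, error = annotate)
}

#' Names of the twelve kinematic parameters
#' @return Character vector in canonical column order.
#' @export
kinematic_feature_names <- function() {
  c("reaction_time", "movement_time", "total_distance", "avg_velocity",
    "max_velocity", "time_to_peak_velocity", "avg_acceleration",
    "max_acceleration", "time_to_peak_acceleration",
    "mu_type1_rms", "mu_type2_rms", "mu_type3_rms")
}

#' Extract features for a list of trials
#'
#' @param trials list of [trial_recording] objects.
#' @param manifest optional manifest data.frame; when given, its score columns
#'   (`vabs_com`, `vabs_dl`, `vabs_soc`) are joined onto the feature table by
#'   `(subject_id, trial_index)`.
#' @param on_error `"stop"` aborts on the first failing trial; `"skip"` drops
#'   failing trials with a warning.
#' @param ... passed to [extract_features()].
#' @return The feature table: one row per trial.
#' @export
extract_cohort_features <- function(trials, manifest = NULL,
                                    on_error = c("stop", "skip"), ...) {
  on_error <- match.arg(on_error)
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    rows[[i]] <- tryCatch(extract_features(trials[[i]], ...),
                          error = function(e) {
                            if (on_error == "stop") stop(e)
                            warning(conditionMessage(e), call. = FALSE)
                            NULL
                          })
  }
  ft <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (!is.null(manifest)) {
    sc <- intersect(c("vabs_com", "vabs_dl", "vabs_soc"), names(manifest))
    if (length(sc) > 0L) {
      key <- paste(ft$subject_id, ft$trial_index)
      mkey <- paste(manifest$subject_id, manifest$trial_index)
      ft[, sc] <- manifest[match(key, mkey), sc]
    }
  }
  rownames(ft) <- NULL
  ft
}
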