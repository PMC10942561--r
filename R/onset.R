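#' Movement-onset detection configuration
#'
#' @param threshold_frac fraction of each signal's window maximum that both
#'   the relative distance and the acceleration magnitude must reach
#'   simultaneously (default 0.2, i.e. the 20% rule).
#' @return An object of class `onset_config`.
#' @export
onset_config <- function(threshold_frac = 0.2) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must lie in (0, 1)", call. = FALSE)
  structure(list(threshold_frac = threshold_frac), class = "onset_config")
}

#' Detect movement onset
#'
#' Movement initiation is the earliest sample in the search window at which
#' both the distance from the starting point and the acceleration magnitude
#' have reached `threshold_frac` of their respective window maxima
#' simultaneously — i.e. the later of the two threshold crossings when each
#' holds persistently.
#'
#' @param pos_mag_rel distance from the starting point, metres, per sample.
#' @param acc_mag acceleration magnitude, m/s^2, per sample.
#' @param t time vector, seconds.
#' @param cfg an [onset_config].
#' @param trigger_time,end_time search window bounds, seconds (default: the
#'   whole recording).
#' @return Onset time in seconds.
#' @export
detect_onset <- function(pos_mag_rel, acc_mag, t, cfg = onset_config(),
                         trigger_time = t[1L], end_time = t[length(t)]) {
  stopifnot(length(pos_mag_rel) == length(t), length(acc_mag) == length(t))
  win <- which(t >= trigger_time - 1e-12 & t <= end_time + 1e-12)
  if (length(win) < 2L) stop("empty onset search window", call. = FALSE)
  pm <- pos_mag_rel[win]
  am <- acc_mag[win]
  if (max(pm) <= 0 || max(am) <= 0)
    stop("no movement in the search window", call. = FALSE)
  ok <- pm >= cfg$threshold_frac * max(pm) & am >= cfg$threshold_frac * max(am)
  hit <- which(ok)
  if (length(hit) == 0L)
    stop("onset thresholds never met simultaneously", call. = FALSE)
  t[win[hit[1L]]]
}

#' Temporal parameters from trial markers
#'
#' Reaction time is the interval between the trial-start cue and the detected
#' movement onset; movement time the interval from onset to the trial end
#' marker.
#'
#' @param onset,trigger,end times in seconds with `trigger <= onset <= end`.
#' @return A list with `reaction_time` and `movement_time` (seconds).
#' @export
compute_temporal_params <- function(onset, trigger, end) {
  if (trigger > onset || onset > end)
    stop("required ordering trigger <= onset <= end violated", call. = FALSE)
  list(reaction_time = onset - trigger, movement_time = end - onset)
}
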