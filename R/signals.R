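#' Signal preparation configuration
#'
#' @param lowpass_cutoff low-pass cutoff in Hz applied zero-phase (two-pass
#'   Butterworth) before differentiation; must stay below the Nyquist
#'   frequency of the recording it is applied to.
#' @param filter_order even Butterworth design order (>= 2) for each pass.
#' @param differentiation only `"central_difference"` is implemented.
#' @param integration_drift drift handling when velocity is reconstructed by
#'   integrating acceleration: `"linear_detrend"` removes the line through the
#'   first and last velocity sample (the hand is at rest at both trial ends),
#'   `"none"` leaves the raw integral.
#' @return An object of class `signal_prep_config`.
#' @export
signal_prep_config <- function(lowpass_cutoff = 10, filter_order = 4,
                               differentiation = "central_difference",
                               integration_drift = c("linear_detrend", "none")) {
  differentiation <- match.arg(differentiation)
  integration_drift <- match.arg(integration_drift)
  if (lowpass_cutoff <= 0) stop("lowpass_cutoff must be > 0", call. = FALSE)
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("filter_order must be even and >= 2", call. = FALSE)
  structure(list(lowpass_cutoff = lowpass_cutoff, filter_order = filter_order,
                 differentiation = differentiation,
                 integration_drift = integration_drift),
            class = "signal_prep_config")
}

# Central difference with one-sided endpoints; works on a vector or the
# columns of a matrix sampled at dt.
central_diff <- function(x, dt) {
  if (is.matrix(x)) {
    n <- nrow(x)
    d <- (x[c(2:n, n), , drop = FALSE] - x[c(1L, 1:(n - 1L)), , drop = FALSE]) /
      (2 * dt)
    d[1L, ] <- (x[2L, ] - x[1L, ]) / dt
    d[n, ] <- (x[n, ] - x[n - 1L, ]) / dt
    return(d)
  }
  n <- length(x)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

# Steady-state initial filter state for a unit-step input (solved from the
# direct-form-II companion recursion), so constants pass through exactly.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1L]
  a <- c(a, rep(0, n - length(a))) / a[1L]
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[2:n]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  solve(diag(n - 1L) - t(comp), b[2:n] - a[2:n] * b[1L])
}

# Zero-phase (forward-backward) filtering with odd-reflection padding at both
# ends so edge transients do not leak into the trial.
filtfilt_pad <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 10L * (length(bf$b) + 1L))
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(front, x, back)
  zi <- filter_zi(bf$b, bf$a)
  yp <- iir_filter_cpp(bf$b, bf$a, xp, zi * xp[1L])
  ypr <- rev(yp)
  yp <- rev(iir_filter_cpp(bf$b, bf$a, ypr, zi * ypr[1L]))
  yp[(pad + 1L):(pad + n)]
}

lowpass_cols <- function(m, cutoff, order, sample_rate) {
  wn <- cutoff / (sample_rate / 2)
  if (wn >= 1)
    stop("lowpass_cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(order, wn, type = "low")
  apply(m, 2L, function(col) filtfilt_pad(bf, col))
}

rownorm <- function(m) sqrt(rowSums(m^2))

#' Prepare the derivative stack for a trial
#'
#' When position is present: zero-phase low-pass filtering of position, then
#' successive central differences give velocity, acceleration and jerk. When
#' only acceleration is present: the acceleration channel is filtered,
#' integrated (trapezoidal) to velocity with endpoint-anchored linear drift
#' removal, then integrated again to position; jerk is differentiated from
#' the filtered acceleration.
#'
#' @param rec a [trial_recording].
#' @param cfg a [signal_prep_config].
#' @param use_channel `"auto"` prefers position when present; `"acc"` forces
#'   the integration path.
#' @return A list with `t`, `T x 3` matrices `pos`, `vel`, `acc`, `jerk`,
#'   their Euclidean magnitude vectors `vel_mag`, `acc_mag`, `jerk_mag`, and
#'   `sample_rate`.
#' @export
prepare_signals <- function(rec, cfg = signal_prep_config(),
                            use_channel = c("auto", "acc")) {
  stopifnot(inherits(rec, "trial_recording"), inherits(cfg, "signal_prep_config"))
  use_channel <- match.arg(use_channel)
  n <- length(rec$t)
  if (n < 10L) stop("recording too short (< 10 samples)", call. = FALSE)
  dt <- 1 / rec$sample_rate
  from_pos <- !is.null(rec$pos) && use_channel == "auto"
  if (!from_pos && is.null(rec$acc))
    stop("recording has neither position nor acceleration", call. = FALSE)
  if (from_pos) {
    pos <- lowpass_cols(rec$pos, cfg$lowpass_cutoff, cfg$filter_order,
                        rec$sample_rate)
    vel <- central_diff(pos, dt)
    acc <- central_diff(vel, dt)
    jerk <- central_diff(acc, dt)
  } else {
    acc <- lowpass_cols(rec$acc, cfg$lowpass_cutoff, cfg$filter_order,
                        rec$sample_rate)
    vel <- apply(acc, 2L, function(a) pracma::cumtrapz(rec$t, a)[, 1L])
    if (cfg$integration_drift == "linear_detrend") {
      # the hand is at rest at both ends of the recording; any residual
      # endpoint velocity is integration drift and is removed linearly
      drift <- outer((rec$t - rec$t[1L]) / (rec$t[n] - rec$t[1L]),
                     vel[n, ] - vel[1L, ])
      vel <- sweep(vel - drift, 2L, vel[1L, ])
    }
    pos <- apply(vel, 2L, function(v) pracma::cumtrapz(rec$t, v)[, 1L])
    jerk <- central_diff(acc, dt)
  }
  colnames(pos) <- colnames(vel) <- colnames(acc) <- colnames(jerk) <-
    c("x", "y", "z")
  list(t = rec$t, pos = pos, vel = vel, acc = acc, jerk = jerk,
       vel_mag = rownorm(vel), acc_mag = rownorm(acc), jerk_mag = rownorm(jerk),
       sample_rate = rec$sample_rate)
}
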