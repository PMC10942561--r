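#' Minimum-jerk submovement kernel
#'
#' A single smooth point-to-point submovement. Its position profile along the
#' normalised time \eqn{\tau = (t - t_0)/T} follows the minimum-jerk polynomial
#' \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5}, the trajectory that minimises
#' integrated squared jerk between two rest states. Outside the active window
#' the contribution is clamped: zero before onset, the full displacement after
#' the kernel ends.
#'
#' @param start_time onset of the submovement, seconds.
#' @param duration duration of the submovement, seconds; must be positive.
#' @param displacement length-3 numeric, metres; the net displacement the
#'   kernel contributes along x, y, z.
#' @return An object of class `submovement_kernel`.
#' @examples
#' k <- submovement_kernel(0, 1, c(0.3, 0, 0))
#' @export
submovement_kernel <- function(start_time, duration, displacement) {
  stopifnot(is.numeric(start_time), length(start_time) == 1L, is.finite(start_time),
            is.numeric(duration), length(duration) == 1L, is.finite(duration),
            is.numeric(displacement), length(displacement) == 3L,
            all(is.finite(displacement)))
  if (duration <= 0) stop("submovement duration must be > 0", call. = FALSE)
  structure(list(start_time = as.numeric(start_time),
                 duration = as.numeric(duration),
                 displacement = as.numeric(displacement)),
            class = "submovement_kernel")
}

# Minimum-jerk basis and its first three derivatives w.r.t. tau (dimensionless).
minjerk_s  <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)
minjerk_s1 <- function(tau) 30 * tau^2 * (1 - tau)^2
minjerk_s2 <- function(tau) 60 * tau * (1 - tau) * (1 - 2 * tau)
minjerk_s3 <- function(tau) 60 - 360 * tau + 360 * tau^2

#' Render a set of submovement kernels onto a time grid
#'
#' Sums the analytic position contributions of all kernels and returns the
#' exact analytic derivatives of that sum (no numerical differentiation), so
#' rendered trajectories can serve as closed-form oracles for the feature
#' extractor.
#'
#' @param kernels non-empty list of [submovement_kernel] objects.
#' @param t strictly increasing, uniformly spaced time vector, seconds.
#' @return A list with `T x 3` matrices `pos` (m), `vel` (m/s), `acc` (m/s^2)
#'   and `jerk` (m/s^3).
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' tr <- render_submovements(list(submovement_kernel(0, 1, c(0.3, 0, 0))), t)
#' max(sqrt(rowSums(tr$vel^2)))  # 1.875 * 0.3 / 1 = 0.5625 m/s
#' @export
render_submovements <- function(kernels, t) {
  if (length(kernels) == 0L) stop("at least one kernel is required", call. = FALSE)
  if (length(t) < 2L) stop("time grid needs at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1L])) > 1e-9)
    stop("time vector must be strictly increasing and uniform", call. = FALSE)
  if (!all(vapply(kernels, inherits, logical(1L), "submovement_kernel")))
    stop("kernels must be submovement_kernel objects", call. = FALSE)
  n <- length(t)
  starts <- vapply(kernels, `[[`, numeric(1L), "start_time")
  durs <- vapply(kernels, `[[`, numeric(1L), "duration")
  disp <- t(vapply(kernels, `[[`, numeric(3L), "displacement"))  # K x 3
  # each kernel only contributes inside its active window; afterwards its
  # position contribution is the constant full displacement
  rendered <- render_kernels_cpp(starts, durs, disp, t)
  pos <- rendered$pos
  vel <- rendered$vel
  acc <- rendered$acc
  jerk <- rendered$jerk
  colnames(pos) <- colnames(vel) <- colnames(acc) <- colnames(jerk) <-
    c("x", "y", "z")
  list(pos = pos, vel = vel, acc = acc, jerk = jerk)
}
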