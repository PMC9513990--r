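# Minimum-jerk primitives: the idealized bell-shaped reference profile used
# both by the indicator suite (ideal paths) and by the trial simulator.

# Normalized minimum-jerk position s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
mj_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
# and its derivative ds/dtau = 30 tau^2 (1 - tau)^2
mj_ds <- function(tau) 30 * tau^2 * (1 - tau)^2

#' Minimum-jerk point-to-point trajectory
#'
#' Straight-line reach with the minimum-jerk time profile
#' `p(tau) = start + (end - start) (10 tau^3 - 15 tau^4 + 6 tau^5)`;
#' position, velocity and acceleration are all boundary-matched to zero.
#' Peak speed is `1.875 L / D` at the movement midpoint.
#'
#' @param start,end 3-D points (meters).
#' @param duration Movement duration D (s, > 0).
#' @param rate Sampling rate (Hz).
#' @return list with `time`, `position` (n x 3), `speed` (analytic, m/s).
#' @export
#' @examples
#' mj <- min_jerk(c(0, 0, 0), c(0.3, 0, 0), duration = 1, rate = 100)
#' max(mj$speed)  # 1.875 * 0.3 / 1
min_jerk <- function(start, end, duration, rate = 100) {
  stopifnot(duration > 0, rate > 0)
  n <- round(duration * rate) + 1L
  tau <- seq(0, 1, length.out = n)
  s <- mj_s(tau)
  pos <- outer(s, as.numeric(end) - as.numeric(start)) +
    matrix(as.numeric(start), n, 3, byrow = TRUE)
  L <- vnorm(as.numeric(end) - as.numeric(start))
  list(time = tau * duration, position = pos,
       speed = L / duration * mj_ds(tau))
}

# Ideal speed profile over a segment of given length and duration, sampled at
# the same instants as an n-sample recording of that segment.
min_jerk_speed_profile <- function(length_m, duration_s, n) {
  tau <- seq(0, 1, length.out = n)
  length_m / duration_s * mj_ds(tau)
}

# Ideal position along the chord at normalized time tau.
min_jerk_position <- function(start, target, tau) {
  as.numeric(start) + (as.numeric(target) - as.numeric(start)) * mj_s(tau)
}

#' Ideal path for a movement segment
#'
#' The idealized reference: straight chord from the segment start point to the
#' target, traversed with a minimum-jerk speed profile over the segment
#' duration.
#'
#' @param start,target 3-D points (m).
#' @param duration_s Segment duration (s).
#' @return list with `start`, `target`, `length_m`, `duration_s`.
#' @export
ideal_path <- function(start, target, duration_s) {
  list(start = as.numeric(start), target = as.numeric(target),
       length_m = vnorm(as.numeric(target) - as.numeric(start)),
       duration_s = duration_s)
}
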