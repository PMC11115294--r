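#' Minimum-jerk angle profile
#'
#' Smooth point-to-point trajectory minimizing integrated squared jerk, the
#' standard kinematic model of unconstrained human reaching. Used by the
#' trial simulator to drive joint angles between rest and the end pose at the
#' occiput.
#'
#' The profile is \eqn{\theta(t) = \theta_0 + (\theta_1-\theta_0)(10\tau^3 -
#' 15\tau^4 + 6\tau^5)} with \eqn{\tau = t/T}; position, velocity and
#' acceleration are continuous and the velocity and acceleration vanish at
#' both ends. Peak angular velocity is \eqn{1.875\,|\theta_1-\theta_0|/T}.
#'
#' @param theta_start,theta_end boundary angles (deg).
#' @param duration movement time T (s); must be positive.
#' @param fs sampling rate (Hz); must be positive.
#' @return Numeric vector of `round(duration * fs) + 1` angles (deg), from
#'   `theta_start` to `theta_end` inclusive.
#' @examples
#' th <- minimum_jerk_profile(0, 90, 1, 100)
#' th[51]                    # midpoint = 45 by point symmetry
#' max(diff(th)) * 100       # ~ 1.875 * 90 peak velocity (deg/s)
#' @export
minimum_jerk_profile <- function(theta_start, theta_end, duration, fs) {
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0)
    hr_stop("`duration` must be a positive number", "headreach_invalid_argument")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    hr_stop("`fs` must be a positive number", "headreach_invalid_argument")
  n <- round(duration * fs)
  tau <- seq(0, 1, length.out = n + 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  theta_start + (theta_end - theta_start) * s
}
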