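#' Shoulder flexion and abduction angle series
#'
#' Euler decomposition of the upper-arm basis relative to the trunk basis,
#' in the fixed sequence flexion (about the trunk mediolateral axis, positive
#' anterior), then abduction (positive away from the trunk), then axial
#' rotation (computed but not reported). The middle (abduction) angle has
#' full (-180, 180) range; the Euler branch with |flexion| < 90 deg is
#' selected, matching the anatomical workspace of the task. Frames within
#' 1 deg of the decomposition singularity are flagged and, when interior,
#' linearly interpolated from their neighbours.
#'
#' @param bases a [build_segment_bases()] result.
#' @return A data.frame with columns `flex`, `abd`, `axial` (deg) and the
#'   logical `gimbal` flag, one row per frame.
#' @export
shoulder_angles <- function(bases) {
  stopifnot(inherits(bases, "segment_bases"))
  tr <- bases$trunk; ua <- bases$upper_arm
  dotr <- function(a, b) rowSums(a * b)
  R13 <- dotr(tr$x, ua$z); R33 <- dotr(tr$z, ua$z); R23 <- dotr(tr$y, ua$z)
  R21 <- dotr(tr$y, ua$x); R22 <- dotr(tr$y, ua$y)
  R31 <- dotr(tr$z, ua$x); R11 <- dotr(tr$x, ua$x)

  # flexion: R13 and R33 are sin(f)cos(a) and cos(f)cos(a); the branch with
  # |flexion| < 90 is selected. Near the singularity (cos(a) ~ 0) both vanish
  # and flexion is taken from the first basis axis assuming no axial rotation.
  f <- atan2(R13, R33)
  flip <- abs(f) > pi / 2
  f[flip] <- f[flip] - sign(f[flip]) * pi
  gimbal <- sqrt(R13^2 + R33^2) < sin(deg2rad(1))
  f[gimbal] <- atan2(-R31[gimbal], R11[gimbal])

  # abduction: sin(a) = -R23 and cos(a) = R13 sin(f) + R33 cos(f), giving the
  # full (-180, 180) range without an asin fold
  a <- atan2(-R23, R13 * sin(f) + R33 * cos(f))

  g <- atan2(R21, R22)
  g[flip & !gimbal] <- g[flip & !gimbal] - sign(g[flip & !gimbal]) * pi
  g[gimbal] <- 0

  if (any(gimbal)) {   # smooth over flagged interior frames when possible
    interior <- which(gimbal)
    ok <- which(!gimbal)
    if (length(ok) >= 2) {
      f[interior] <- approx(ok, f[ok], xout = interior, rule = 2)$y
      a[interior] <- approx(ok, a[ok], xout = interior, rule = 2)$y
    }
  }
  data.frame(flex = -rad2deg(f), abd = -rad2deg(a), axial = rad2deg(g),
             gimbal = gimbal)
}

#' Elbow flexion angle series
#'
#' Angle between the prolongation of the upper arm (acromion-to-olecranon
#' line extended) and the forearm long axis; 0 deg at full extension.
#'
#' @param bases a [build_segment_bases()] result.
#' @return Numeric vector of elbow flexion angles (deg), in `[0, 180]`.
#' @export
elbow_flexion <- function(bases) {
  stopifnot(inherits(bases, "segment_bases"))
  prol <- -bases$upper_arm$z
  w <- bases$wrist_dir
  cr <- row_cross(prol, w)
  rad2deg(atan2(sqrt(rowSums(cr^2)), rowSums(prol * w)))
}

#' Angular velocity by finite differences
#'
#' Central finite difference scaled by the sampling rate, with one-sided
#' differences at the endpoints. The sign of the rate is preserved; negative
#' values are admissible.
#'
#' @param angle_series numeric vector of joint angles (deg).
#' @param fs sampling rate (Hz).
#' @return Angular velocity series (deg/s) of the same length.
#' @examples
#' angular_velocity(seq(0, 90, length.out = 101), fs = 100)[50]  # 90 deg/s
#' @export
angular_velocity <- function(angle_series, fs) {
  n <- length(angle_series)
  if (n < 3)
    hr_stop("angular velocity needs at least 3 samples",
            "headreach_invalid_argument")
  v <- numeric(n)
  v[2:(n - 1)] <- (angle_series[3:n] - angle_series[1:(n - 2)]) * fs / 2
  v[1] <- (angle_series[2] - angle_series[1]) * fs
  v[n] <- (angle_series[n] - angle_series[n - 1]) * fs
  v
}
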