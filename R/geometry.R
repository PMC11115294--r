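#' Arm and trunk segment geometry
#'
#' Body-segment dimensions carrying the upper-body marker subset. Defaults
#' are scaled from stature with standard anthropometric segment fractions
#' (upper arm 0.186 H, forearm 0.146 H, hand 0.108 H) using the cohort
#' median height of 169 cm.
#'
#' @param height_mm stature in mm used to scale the default segment lengths.
#' @param upper_arm_length,forearm_length,hand_length segment lengths in mm.
#' @param shoulder_offset_from_c7 length-3 vector (mm), position of the
#'   acromion relative to C7 in the canonical frame (x anterior, y left,
#'   z up) for a right limb; mirrored internally for a left limb.
#' @param trunk_height height of C7 above the seat plane (mm).
#' @return An object of class `arm_geometry` (named list).
#' @examples
#' arm_geometry()                 # cohort-median adult
#' arm_geometry(height_mm = 1540) # shorter participant
#' @export
arm_geometry <- function(height_mm = 1690,
                         upper_arm_length = 0.186 * height_mm,
                         forearm_length = 0.146 * height_mm,
                         hand_length = 0.108 * height_mm,
                         shoulder_offset_from_c7 = c(20, -0.12 * height_mm, -10),
                         trunk_height = 600) {
  lens <- c(upper_arm_length = upper_arm_length,
            forearm_length = forearm_length,
            hand_length = hand_length,
            trunk_height = trunk_height)
  if (any(!is.finite(lens)) || any(lens <= 0))
    hr_stop("all segment lengths must be positive and finite",
            "headreach_invalid_argument")
  if (length(shoulder_offset_from_c7) != 3)
    hr_stop("`shoulder_offset_from_c7` must be a length-3 vector",
            "headreach_invalid_argument")
  structure(list(upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 hand_length = hand_length,
                 shoulder_offset_from_c7 = as.numeric(shoulder_offset_from_c7),
                 trunk_height = trunk_height),
            class = "arm_geometry")
}

# elementary rotation matrices (right-handed, angles in radians)
rot_x <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# Shoulder rotation for the canonical right limb: intrinsic sequence
# flexion (about trunk mediolateral axis, positive anterior), then abduction
# (positive lateral, i.e. toward -y), then axial rotation. In the canonical
# frame x is anterior, y left, z up; the arm hangs along -z at zero pose.
shoulder_rotation <- function(flex_deg, abd_deg, axial_deg = 0) {
  rot_y(-deg2rad(flex_deg)) %*% rot_x(-deg2rad(abd_deg)) %*%
    rot_z(deg2rad(axial_deg))
}

# Inverse of shoulder_rotation: recover (flex, abd, axial) in degrees from a
# relative rotation matrix. The middle (abduction) angle has full range
# (-180, 180); the branch with |flexion| < 90 is selected, matching the
# anatomical workspace of this task. Near the decomposition singularity
# (|cos(abd)| ~ 0) flexion and axial rotation are coupled; axial is set to 0
# there and the frame flagged.
#' @noRd
euler_yxz_angles <- function(R, gimbal_tol = cos(deg2rad(89))) {
  f <- atan2(R[1, 3], R[3, 3])
  a <- asin(min(1, max(-1, -R[2, 3])))
  gimbal <- FALSE
  if (abs(cos(a)) < gimbal_tol || (abs(R[1, 3]) < 1e-12 && abs(R[3, 3]) < 1e-12)) {
    # gimbal: assign all in-plane rotation to flexion
    gimbal <- TRUE
    f <- atan2(-R[3, 1], R[1, 1])
    g <- 0
  } else {
    g <- atan2(R[2, 1], R[2, 2])
    if (abs(f) > pi / 2) {       # other Euler branch: |flex| < 90 preferred
      f <- f - sign(f) * pi
      a <- sign(a) * pi - a
      g <- g - sign(g) * pi
    }
  }
  c(flex = -rad2deg(f), abd = -rad2deg(a), axial = rad2deg(g),
    gimbal = as.numeric(gimbal))
}

#' Forward kinematics of the upper limb for one frame
#'
#' Places the upper-body markers of a canonical right limb for a given
#' shoulder flexion/abduction and elbow flexion, in a lab frame with x
#' anterior, y left, z up and the arm hanging along the trunk (elbow
#' extended) at the zero pose. Elbow flexion rotates the forearm anteriorly
#' in the upper-arm frame; 0 deg is full extension.
#'
#' This is the exact inverse of the marker-based Euler angle extraction
#' (see [shoulder_angles()] and [elbow_flexion()]), which is pinned by
#' round-trip tests.
#'
#' @param geometry an [arm_geometry()] object.
#' @param shoulder_flex,shoulder_abd,elbow_flex joint angles in degrees,
#'   each within (-180, 180).
#' @param axial axial (internal/external) shoulder rotation in degrees;
#'   computed but not among the reported features.
#' @return Named list of length-3 marker positions (mm): `C7`, `CLAV`,
#'   `RBHD`, `LBHD`, `RSHO`, `RELB`, `RWRA`, `RWRB`, `RFIN`.
#' @examples
#' fk <- forward_kinematics(arm_geometry(), 0, 0, 0)
#' fk$RSHO - fk$RELB   # arm hangs straight down: offset (0, 0, L_upper)
#' @export
forward_kinematics <- function(geometry, shoulder_flex, shoulder_abd,
                               elbow_flex, axial = 0) {
  if (!inherits(geometry, "arm_geometry"))
    hr_stop("`geometry` must be an arm_geometry object",
            "headreach_invalid_argument")
  ang <- c(shoulder_flex, shoulder_abd, elbow_flex)
  if (any(!is.finite(ang)) || any(abs(ang) >= 180))
    hr_stop("joint angles must lie within (-180, 180) degrees",
            "headreach_invalid_argument")
  c7 <- c(0, 0, geometry$trunk_height)
  clav <- c7 + c(80, 0, -30)
  rbhd <- c7 + c(-60, -35, 80)
  lbhd <- c7 + c(-60, 35, 80)
  sho <- c7 + geometry$shoulder_offset_from_c7
  R_sh <- shoulder_rotation(shoulder_flex, shoulder_abd, axial)
  elb <- sho + geometry$upper_arm_length * as.numeric(R_sh %*% c(0, 0, -1))
  R_fa <- R_sh %*% rot_y(-deg2rad(elbow_flex))
  fa_dir <- as.numeric(R_fa %*% c(0, 0, -1))
  wrist <- elb + geometry$forearm_length * fa_dir
  wr_off <- 25 * as.numeric(R_fa %*% c(0, 1, 0))
  fin <- wrist + geometry$hand_length * fa_dir
  list(C7 = c7, CLAV = clav, RBHD = rbhd, LBHD = lbhd, RSHO = sho,
       RELB = elb, RWRA = wrist + wr_off, RWRB = wrist - wr_off, RFIN = fin)
}
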