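# marker aliasing: map equivalent marker names onto the canonical set
marker_aliases <- c(RSH = "RSHO", LSH = "LSHO", STRN = "CLAV")

required_canonical <- c("SHO", "ELB", "WRA", "WRB", "FIN", "CLAV", "C7", "BHD")

# Reduce a trial to canonical right-limb marker matrices: alias names,
# infer the measured limb from the R*/L* prefixes, mirror left-limb trials
# across the sagittal plane, and pick the side-matched occiput marker.
canonical_markers <- function(trial) {
  mk <- trial$markers
  nm <- names(mk)
  names(mk)[nm %in% names(marker_aliases)] <-
    marker_aliases[nm[nm %in% names(marker_aliases)]]
  limb <- if (!is.null(trial$limb)) trial$limb
          else if ("RELB" %in% names(mk)) "right"
          else if ("LELB" %in% names(mk)) "left"
          else hr_stop("cannot infer measured limb: no RELB/LELB marker",
                       "headreach_missing_marker")
  if (limb == "left") mk <- mirror_markers(mk)
  pick <- function(name) {
    full <- paste0("R", name)
    if (full %in% names(mk)) return(mk[[full]])
    if (name %in% names(mk)) return(mk[[name]])
    hr_stop(sprintf("required marker missing: %s (limb %s)",
                    if (limb == "left") paste0("L", name) else full, limb),
            "headreach_missing_marker")
  }
  out <- list(SHO = pick("SHO"), ELB = pick("ELB"), WRA = pick("WRA"),
              WRB = pick("WRB"), FIN = pick("FIN"),
              CLAV = if ("CLAV" %in% names(mk)) mk$CLAV else
                hr_stop("required marker missing: CLAV",
                        "headreach_missing_marker"),
              C7 = if ("C7" %in% names(mk)) mk$C7 else
                hr_stop("required marker missing: C7",
                        "headreach_missing_marker"),
              BHD = pick("BHD"))
  out
}

unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build per-frame trunk, upper-arm and forearm segment bases
#'
#' Constructs time-indexed orthonormal segment coordinate frames from the
#' upper-body marker subset, in the canonical frame (x anterior, y left,
#' z up; left-limb trials are mirrored first):
#' \itemize{
#'   \item trunk: anterior axis from C7 to the manubrium (CLAV), vertical
#'     axis the lab vertical orthogonalized against it;
#'   \item upper arm: long axis from the olecranon to the acromion, second
#'     axis in the arm/forearm plane;
#'   \item forearm: long axis from the olecranon to the wrist-marker
#'     midpoint.
#' }
#' With the elbow near full extension the arm/forearm plane is undefined
#' (the shoulder's axial rotation is unobservable from these markers); the
#' in-plane axis then falls back to the trunk anterior axis projected
#' orthogonal to the arm. Joint angles of interest (shoulder
#' flexion/abduction, elbow flexion) do not depend on that axis. A frame
#' with coincident markers (zero-length segment) raises a degenerate-frame
#' error naming the frame.
#'
#' @param trial a `trial_recording`, or a canonical marker list as produced
#'   internally (advanced use).
#' @return An object of class `segment_bases`: per-segment lists of n x 3
#'   unit-axis matrices (`x`, `y`, `z`), plus `fs` and `n`.
#' @export
build_segment_bases <- function(trial) {
  mk <- if (inherits(trial, "trial_recording")) canonical_markers(trial)
        else trial
  fs <- if (inherits(trial, "trial_recording")) trial$sampling_rate else NA
  n <- nrow(mk$C7)

  check_len <- function(v, what) {
    nrm <- sqrt(rowSums(v^2))
    bad <- which(nrm < 1e-9)
    if (length(bad) > 0)
      hr_stop(sprintf("degenerate frame %d: %s markers coincide", bad[1], what),
              "headreach_degenerate_frame")
    v
  }

  # trunk: gravity vertical is the longitudinal axis (seated, still trunk);
  # anterior axis is the horizontal component of C7 -> manubrium
  ant <- check_len(mk$CLAV - mk$C7, "trunk")
  tz <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  tx <- unit_rows(check_len(ant - rowSums(ant * tz) * tz, "trunk axis"))
  ty <- row_cross(tz, tx)

  # upper arm
  uz <- unit_rows(check_len(mk$SHO - mk$ELB, "upper arm"))
  wrist <- (mk$WRA + mk$WRB) / 2
  w <- unit_rows(check_len(wrist - mk$ELB, "forearm"))
  ux_raw <- w - rowSums(w * uz) * uz
  res <- sqrt(rowSums(ux_raw^2))
  collinear <- res < 1e-8
  if (any(collinear)) {   # extended elbow: axial rotation unobservable
    fb <- tx - rowSums(tx * uz) * uz
    ux_raw[collinear, ] <- fb[collinear, ]
  }
  ux <- unit_rows(check_len(ux_raw, "upper-arm plane"))
  uy <- row_cross(uz, ux)

  # forearm (long axis only is needed downstream; reuse arm plane)
  fz <- w
  fx_raw <- ux - rowSums(ux * fz) * fz
  fx <- unit_rows(check_len(fx_raw, "forearm plane"))
  fy <- row_cross(fz, fx)

  structure(list(trunk = list(x = tx, y = ty, z = tz),
                 upper_arm = list(x = ux, y = uy, z = uz),
                 forearm = list(x = fx, y = fy, z = fz),
                 wrist_dir = w, n = n, fs = fs),
            class = "segment_bases")
}
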