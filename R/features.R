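#' Feature-extraction configuration
#'
#' Tunable parameters of the kinematic feature extraction. Defaults follow
#' standard practice for 100 Hz optical capture: a 6 Hz zero-phase
#' Butterworth low-pass (order 4) before differentiation, and a 5 mm/s
#' sustained-speed rule (0.2 s window) for movement segmentation.
#'
#' @param filter_cutoff low-pass cutoff (Hz); `NULL` disables filtering
#'   (useful for noiseless synthetic data).
#' @param filter_order Butterworth order.
#' @param speed_eps segmentation speed threshold (mm/s).
#' @param window_s segmentation window (s).
#' @param velocity_mode `"per_frame"` (peak of the frame-wise derivative,
#'   default) or `"phase_average"` (net angle change divided by the phase
#'   motor time). Reported peak velocities are incompatible with a single
#'   phase-averaged quotient, hence the per-frame default; both are exposed.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(filter_cutoff = 6, filter_order = 4,
                           speed_eps = 5, window_s = 0.2,
                           velocity_mode = c("per_frame", "phase_average")) {
  velocity_mode <- match.arg(velocity_mode)
  structure(list(filter_cutoff = filter_cutoff, filter_order = filter_order,
                 speed_eps = speed_eps, window_s = window_s,
                 velocity_mode = velocity_mode),
            class = "feature_config")
}

#' Extract per-phase kinematic features from one trial
#'
#' Runs the full per-trial chain: marker canonicalization (aliasing,
#' left-limb mirroring), zero-phase low-pass filtering, segmentation of the
#' outward and return phases from the index-finger marker, segment bases and
#' Euler joint angles, frame-wise angular velocities, and per-phase scalar
#' features:
#' \itemize{
#'   \item motor time: (end - onset) / fs per phase;
#'   \item peak shoulder flexion, shoulder abduction, elbow flexion angles
#'     (maximum within the phase, deg);
#'   \item peak angular velocities (deg/s), taken as the maximum rate of
#'     change in the phase's direction of travel (outward +d/dt, return
#'     -d/dt), so large positive values mean fast motion in the phase
#'     direction and small negative values are admissible;
#'   \item maximum displacement of the manubrium (CLAV) and side-matched
#'     occiput marker from their phase-onset positions (mm).
#' }
#' Trials are never averaged within a participant; each trial contributes
#' one outward and one return row.
#'
#' @param trial a `trial_recording`.
#' @param config a [feature_config()].
#' @return A two-row data.frame (phases `outward`, `return`) with feature
#'   columns plus `participant_id`, `side`, `trial_id` and any metadata
#'   covariates.
#' @export
extract_features <- function(trial, config = feature_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  tid <- if (!is.null(trial$trial_id)) trial$trial_id else trial$participant_id
  res <- tryCatch(
    extract_features_impl(trial, config),
    headreach_error = function(e) {
      hr_stop(sprintf("trial %s: %s", tid, conditionMessage(e)),
              class(e)[1])
    })
  res
}

extract_features_impl <- function(trial, config) {
  fs <- trial$sampling_rate
  mk <- canonical_markers(trial)
  if (!is.null(config$filter_cutoff))
    mk <- lapply(mk, lowpass_filter, fs = fs,
                 cutoff_hz = config$filter_cutoff,
                 order = config$filter_order)

  bounds <- detect_motion_bounds(mk$FIN, fs, speed_eps = config$speed_eps,
                                 window_s = config$window_s)
  bases <- build_segment_bases(mk)
  bases$fs <- fs
  sh <- shoulder_angles(bases)
  el <- elbow_flexion(bases)
  ang <- cbind(shoulder_flex = sh$flex, shoulder_abd = sh$abd,
               elbow_flex = el)
  vel <- apply(ang, 2, angular_velocity, fs = fs)

  one_phase <- function(b, dir_sign) {
    idx <- b$onset_frame:b$end_frame
    motor_time <- (b$end_frame - b$onset_frame) / fs
    peaks <- apply(ang[idx, , drop = FALSE], 2, max)
    pv <- if (config$velocity_mode == "per_frame") {
      apply(dir_sign * vel[idx, , drop = FALSE], 2, max)
    } else {
      abs(ang[b$end_frame, ] - ang[b$onset_frame, ]) / motor_time
    }
    data.frame(phase = b$phase, motor_time = motor_time,
               peak_shoulder_flex = peaks[["shoulder_flex"]],
               peak_shoulder_abd = peaks[["shoulder_abd"]],
               peak_elbow_flex = peaks[["elbow_flex"]],
               peak_vel_shoulder_flex = pv[["shoulder_flex"]],
               peak_vel_shoulder_abd = pv[["shoulder_abd"]],
               peak_vel_elbow_flex = pv[["elbow_flex"]],
               disp_manubrium = marker_displacement(mk$CLAV, b),
               disp_occiput = marker_displacement(mk$BHD, b))
  }
  out <- rbind(one_phase(bounds$outward, 1), one_phase(bounds$ret, -1))
  out$participant_id <- trial$participant_id
  out$side <- trial$side
  out$trial_id <- if (!is.null(trial$trial_id)) trial$trial_id else NA_character_
  for (nm in names(trial$metadata)) out[[nm]] <- trial$metadata[[nm]]
  rownames(out) <- NULL
  out
}

#' Extract features for a whole cohort
#'
#' Applies [extract_features()] to every trial and binds the per-phase rows
#' into one pooled feature table (one row per trial x phase).
#'
#' @param trials list of `trial_recording` objects.
#' @param config a [feature_config()].
#' @return A data.frame feature table.
#' @export
extract_cohort_features <- function(trials, config = feature_config()) {
  do.call(rbind, lapply(trials, extract_features, config = config))
}
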