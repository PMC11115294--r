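#' @noRd
trial_recording <- function(participant_id, side, limb, sampling_rate,
                            markers, metadata = list()) {
  len <- vapply(markers, nrow, integer(1))
  if (length(unique(len)) != 1)
    hr_stop("all marker series must have equal length",
            "headreach_invalid_argument")
  structure(list(participant_id = participant_id, side = side, limb = limb,
                 sampling_rate = sampling_rate, markers = markers,
                 metadata = metadata),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- nrow(x$markers[[1]])
  cat(sprintf(
    "<trial_recording> %s (%s limb, %s side): %d markers x %d frames @ %g Hz\n",
    x$participant_id, x$limb, x$side, length(x$markers), n, x$sampling_rate))
  invisible(x)
}

n_frames <- function(trial) nrow(trial$markers[[1]])

# piecewise angle trajectory: rest / outward min-jerk / hold / return / rest
angle_trajectory <- function(peak, t, t_on, t_out, hold, t_ret) {
  s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  out <- numeric(length(t))
  ph1 <- t >= t_on & t < t_on + t_out
  out[ph1] <- peak * s((t[ph1] - t_on) / t_out)
  ph2 <- t >= t_on + t_out & t < t_on + t_out + hold
  out[ph2] <- peak
  t_r0 <- t_on + t_out + hold
  ph3 <- t >= t_r0 & t < t_r0 + t_ret
  out[ph3] <- peak * (1 - s((t[ph3] - t_r0) / t_ret))
  out
}

# mirror a marker map across the sagittal plane and swap R/L prefixes
mirror_markers <- function(markers) {
  mirrored <- lapply(markers, function(m) {
    m[, 2] <- -m[, 2]
    m
  })
  nm <- names(mirrored)
  swapped <- ifelse(grepl("^R", nm), sub("^R", "L", nm),
                    ifelse(grepl("^L", nm), sub("^L", "R", nm), nm))
  names(mirrored) <- swapped
  mirrored
}

# Synthesize the noise-free marker trajectories for given movement times and
# end pose. Returns the marker map plus the time grid.
synth_markers <- function(geometry, params, t_out, t_ret, flex, abd, elbow,
                          fs) {
  total <- params$rest_pre_s + t_out + params$hold_s + t_ret +
    params$rest_post_s
  nf <- round(total * fs) + 1
  t <- (seq_len(nf) - 1) / fs
  t_on <- params$rest_pre_s

  F_t <- deg2rad(angle_trajectory(flex, t, t_on, t_out, params$hold_s, t_ret))
  A_t <- deg2rad(angle_trajectory(abd, t, t_on, t_out, params$hold_s, t_ret))
  E_t <- deg2rad(angle_trajectory(elbow, t, t_on, t_out, params$hold_s, t_ret))

  sF <- sin(F_t); cF <- cos(F_t)
  sA <- sin(A_t); cA <- cos(A_t)
  sE <- sin(E_t); cE <- cos(E_t)

  # canonical right-limb frames: arm axis u, forearm axis d, arm-frame y
  u <- cbind(sF * cA, -sA, -cF * cA)
  d <- cbind(sE * cF + cE * sF * cA, -cE * sA, sE * sF - cE * cF * cA)
  ay <- cbind(sF * sA, cA, -cF * sA)

  c7 <- c(0, 0, geometry$trunk_height)
  sho0 <- c7 + geometry$shoulder_offset_from_c7
  rep_row <- function(v) matrix(v, nf, 3, byrow = TRUE)
  sho <- rep_row(sho0)
  elb <- sho + geometry$upper_arm_length * u
  wrist <- elb + geometry$forearm_length * d
  wr_off <- 25 * ay
  fin <- wrist + geometry$hand_length * d
  list(markers = list(
         C7 = rep_row(c7),
         CLAV = rep_row(c7 + c(80, 0, -30)),
         RBHD = rep_row(c7 + c(-60, -35, 80)),
         LBHD = rep_row(c7 + c(-60, 35, 80)),
         RSHO = sho, RELB = elb,
         RWRA = wrist + wr_off, RWRB = wrist - wr_off, RFIN = fin),
       t = t, nf = nf)
}

#' Simulate one occiput-reaching trial
#'
#' Synthesizes the upper-body marker trajectories of a single seated reach to
#' the back of the head: a still pre-phase, an outward minimum-jerk motion of
#' the shoulder (flexion + abduction) and elbow toward a sampled end pose at
#' the occiput, a brief hold, a minimum-jerk return to the hanging-arm rest
#' pose, and a still post-phase. Trunk and head marker clusters oscillate
#' with a 0.3 Hz postural sway of configurable amplitude, and white noise of
#' sd `params$marker_noise_sd` is added to every marker coordinate.
#'
#' Movement times and the end-pose angles are drawn per trial from truncated
#' normal distributions; a non-positive draw is impossible by construction
#' (truncation bounds are strictly positive).
#'
#' The motor-time parameters are defined as the *rule-detected* durations
#' (the segmentation rule of [detect_motion_bounds()] cannot see the
#' sub-threshold tails of a smooth velocity profile, and published motor
#' times are themselves rule-detected). The simulator therefore calibrates
#' each trial in a noise-free first pass: it measures the detected duration
#' at the calibration threshold and stretches the underlying profile so that
#' the detected motor time matches the sampled one.
#'
#' @param geometry an [arm_geometry()] object.
#' @param params a [sided_motion_params()] object.
#' @param targets optional list with elements `flex`, `abd`, `elbow`,
#'   `t_out`, `t_ret` overriding the sampled end pose and movement times.
#' @param seed integer seed; identical seeds give bitwise-identical trials.
#' @param participant_id,side,limb labels stored in the recording; `limb`
#'   selects the physical side ("right" markers or mirrored "left" markers).
#' @param fs sampling rate (Hz).
#' @param metadata named list of participant covariates (sex, age, bmi,
#'   months_post_onset) carried through to the feature table.
#' @param calibration_eps segmentation speed threshold (mm/s) the motor-time
#'   parameters are calibrated against; should match the `speed_eps` used at
#'   extraction. Set to `NULL` to skip calibration (the profile duration is
#'   then the sampled motor time exactly).
#' @return A `trial_recording`.
#' @examples
#' tr <- simulate_trial(arm_geometry(), default_motion_params("paralyzed"),
#'                      seed = 1)
#' tr
#' @export
simulate_trial <- function(geometry, params, targets = NULL, seed = NULL,
                           participant_id = "P01", side = "paralyzed",
                           limb = c("right", "left"), fs = 100,
                           metadata = list(), calibration_eps = 5) {
  limb <- match.arg(limb)
  stopifnot(inherits(geometry, "arm_geometry"),
            inherits(params, "sided_motion_params"))
  with_seed(seed, {
    t_out <- if (!is.null(targets$t_out)) targets$t_out else
      rtruncnorm(1, params$motor_time_mean, params$motor_time_sd, 0.9, 8)
    t_ret <- if (!is.null(targets$t_ret)) targets$t_ret else
      rtruncnorm(1, params$motor_time_return_mean,
                 params$motor_time_return_sd, 0.9, 8)
    flex <- if (!is.null(targets$flex)) targets$flex else
      rtruncnorm(1, params$peak_shoulder_flex[1], params$peak_shoulder_flex[2],
                 2, 88)
    abd <- if (!is.null(targets$abd)) targets$abd else
      rtruncnorm(1, params$peak_shoulder_abd[1], params$peak_shoulder_abd[2],
                 10, 168)
    elbow <- if (!is.null(targets$elbow)) targets$elbow else
      rtruncnorm(1, params$peak_elbow_flex[1], params$peak_elbow_flex[2],
                 20, 149.5)

    # calibration pass: stretch the profile so the rule-detected durations
    # equal the sampled motor times
    t_out_p <- t_out; t_ret_p <- t_ret
    if (!is.null(calibration_eps)) {
      for (iter in 1:3) {
        cal <- synth_markers(geometry, params, t_out_p, t_ret_p, flex, abd,
                             elbow, fs)
        det <- tryCatch(
          detect_motion_bounds(lowpass_filter(cal$markers$RFIN, fs), fs,
                               speed_eps = calibration_eps),
          headreach_error = function(e) NULL)
        if (is.null(det)) break
        err_out <- t_out - (det$outward$end_frame - det$outward$onset_frame) / fs
        err_ret <- t_ret - (det$ret$end_frame - det$ret$onset_frame) / fs
        if (abs(err_out) < 0.01 && abs(err_ret) < 0.01) break
        t_out_p <- max(0.3, t_out_p + err_out)
        t_ret_p <- max(0.3, t_ret_p + err_ret)
      }
    }

    syn <- synth_markers(geometry, params, t_out_p, t_ret_p, flex, abd,
                         elbow, fs)
    markers <- syn$markers
    t <- syn$t; nf <- syn$nf

    # shared trunk-cluster sway and independent head sway (translations)
    sway <- function(amp) {
      dir <- c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)), 0)
      phase <- runif(1, 0, 2 * pi)
      wobble <- amp * sin(2 * pi * 0.3 * t + phase)
      outer(wobble, dir)
    }
    trunk_sway <- sway(params$trunk_sway_amp)
    head_sway <- trunk_sway + sway(params$head_sway_amp)
    # sway enters the analysis only through the displacement covariates, so
    # it is applied to the trunk/head cluster and not to the arm chain
    for (m in c("C7", "CLAV"))
      markers[[m]] <- markers[[m]] + trunk_sway
    for (m in c("RBHD", "LBHD"))
      markers[[m]] <- markers[[m]] + head_sway

    if (params$marker_noise_sd > 0)
      markers <- lapply(markers, function(m)
        m + matrix(rnorm(length(m), 0, params$marker_noise_sd), nrow(m)))
    if (limb == "left") markers <- mirror_markers(markers)

    trial_recording(participant_id, side, limb, fs, markers, metadata)
  })
}

#' Generate a simulated study cohort
#'
#' Simulates `n_participants x 2 sides x trials_per_side` occiput-reaching
#' trials. Participant covariates (sex, age, BMI, months post-onset,
#' stature-scaled geometry) are sampled once per participant and shared by
#' all of that participant's trials; the paralyzed side is always the right
#' limb, matching the study cohort. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `trial_recording` objects.
#' @examples
#' trials <- generate_cohort(cohort_spec(n_participants = 2,
#'                                       trials_per_side = 1, seed = 7))
#' length(trials)  # 2 participants x 2 sides x 1 trial
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    trials <- list()
    for (i in seq_len(spec$n_participants)) {
      pid <- sprintf("P%02d", i)
      sex <- sample(c("F", "M"), 1, prob = c(0.3, 0.7))
      height <- if (sex == "F") rtruncnorm(1, 1540, 50, 1400, 1700) else
        rtruncnorm(1, 1700, 50, 1550, 1900)
      meta <- list(sex = sex,
                   age = round(rtruncnorm(1, 48, 8, 25, 75)),
                   bmi = round(rtruncnorm(1, 24, 3, 17, 35), 1),
                   months_post_onset = round(exp(rnorm(1, log(54), 0.55))))
      geom <- if (is.null(spec$geometry)) arm_geometry(height_mm = height)
              else spec$geometry
      for (side in c("paralyzed", "non_paralyzed")) {
        par_side <- if (side == "paralyzed") spec$paralyzed_params else
          spec$nonparalyzed_params
        limb <- if (side == "paralyzed") "right" else "left"
        for (k in seq_len(spec$trials_per_side)) {
          tr <- simulate_trial(geom, par_side, participant_id = pid,
                               side = side, limb = limb, metadata = meta)
          tr$trial_id <- sprintf("%s_%s_T%d", pid, side, k)
          trials[[length(trials) + 1L]] <- tr
        }
      }
    }
    trials
  })
}
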