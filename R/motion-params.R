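#' Side-dependent motion parameters
#'
#' Distributional parameters of one limb's occiput-reaching kinematics, used
#' by [simulate_trial()]. Per-trial movement times and peak joint angles are
#' drawn from truncated normal distributions (truncation at wide anatomical
#' bounds) so that simulated cohorts reproduce the reported side-dependent
#' feature distributions of the clinical task.
#'
#' @param motor_time_mean,motor_time_sd outward-phase movement time (s).
#' @param motor_time_return_mean,motor_time_return_sd return-phase movement
#'   time (s); the return is slightly slower on the non-paralyzed side.
#' @param peak_shoulder_flex,peak_shoulder_abd,peak_elbow_flex length-2
#'   vectors `c(mean, sd)` of the end-pose joint angles (deg).
#' @param trunk_sway_amp,head_sway_amp amplitude (mm) of the low-frequency
#'   (0.3 Hz) postural sway added to the trunk and head marker clusters.
#' @param marker_noise_sd white marker noise (mm) added per coordinate.
#' @param rest_pre_s,rest_post_s,hold_s still periods before the outward
#'   motion, at the occiput, and after the return (s).
#' @return An object of class `sided_motion_params`.
#' @seealso [default_motion_params()] for the study-condition defaults.
#' @export
sided_motion_params <- function(motor_time_mean, motor_time_sd,
                                motor_time_return_mean = motor_time_mean,
                                motor_time_return_sd = motor_time_sd,
                                peak_shoulder_flex = c(45, 12),
                                peak_shoulder_abd = c(118, 10),
                                peak_elbow_flex = c(137, 7),
                                trunk_sway_amp = 2.5,
                                head_sway_amp = 5,
                                marker_noise_sd = 0.05,
                                rest_pre_s = 0.5,
                                rest_post_s = 0.5,
                                hold_s = 0.5) {
  if (motor_time_mean <= 0 || motor_time_return_mean <= 0)
    hr_stop("motor time means must be positive", "headreach_invalid_argument")
  sds <- c(motor_time_sd, motor_time_return_sd, peak_shoulder_flex[2],
           peak_shoulder_abd[2], peak_elbow_flex[2])
  if (any(sds < 0))
    hr_stop("standard deviations must be non-negative",
            "headreach_invalid_argument")
  if (peak_elbow_flex[1] >= 150)
    hr_stop("mean peak elbow flexion must stay below the 150 deg anatomical bound",
            "headreach_invalid_argument")
  if (marker_noise_sd < 0 || trunk_sway_amp < 0 || head_sway_amp < 0)
    hr_stop("noise and sway amplitudes must be non-negative",
            "headreach_invalid_argument")
  structure(as.list(environment()), class = "sided_motion_params")
}

#' Study-condition motion parameter defaults
#'
#' Default [sided_motion_params()] for the paralyzed and non-paralyzed upper
#' limb, taken from the reported descriptive statistics of the clinical
#' occiput-reaching cohort (mean/SD of motor time and peak joint angles per
#' side and phase). Sway amplitudes are set so that the expected within-phase
#' maximum marker excursion is near the reported displacement means.
#'
#' @param side `"paralyzed"` or `"non_paralyzed"`.
#' @return A `sided_motion_params` object.
#' @examples
#' default_motion_params("paralyzed")$motor_time_mean      # 2.3 s
#' default_motion_params("non_paralyzed")$motor_time_mean  # 1.3 s
#' @export
default_motion_params <- function(side = c("paralyzed", "non_paralyzed")) {
  side <- match.arg(side)
  if (side == "paralyzed") {
    sided_motion_params(
      motor_time_mean = 2.3, motor_time_sd = 0.7,
      motor_time_return_mean = 2.3, motor_time_return_sd = 0.7,
      peak_shoulder_flex = c(48.9, 15.4),
      peak_shoulder_abd = c(117.5, 16.7),
      peak_elbow_flex = c(134.2, 8.0),
      trunk_sway_amp = 3.4, head_sway_amp = 6.4)
  } else {
    sided_motion_params(
      motor_time_mean = 1.3, motor_time_sd = 0.3,
      motor_time_return_mean = 1.5, motor_time_return_sd = 0.3,
      peak_shoulder_flex = c(42.3, 11.2),
      peak_shoulder_abd = c(118.9, 6.2),
      peak_elbow_flex = c(140.0, 6.1),
      trunk_sway_amp = 2.0, head_sway_amp = 4.1)
  }
}

#' Cohort specification
#'
#' Describes a simulated study cohort: number of participants, trials per
#' limb, the per-side motion parameters and the random seed. The default
#' matches the clinical study design: 10 participants, 2 sides, 5 trials per
#' side (100 trials). All participants are simulated with right-side
#' paralysis, as in the study cohort.
#'
#' @param n_participants number of participants (>= 1).
#' @param trials_per_side trials recorded per limb (>= 1).
#' @param paralyzed_params,nonparalyzed_params [sided_motion_params()] per side.
#' @param geometry optional [arm_geometry()] shared by all participants;
#'   `NULL` scales geometry from each participant's sampled stature.
#' @param seed integer seed fixing all randomness of [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 10, trials_per_side = 5,
                        paralyzed_params = default_motion_params("paralyzed"),
                        nonparalyzed_params = default_motion_params("non_paralyzed"),
                        geometry = NULL, seed = 1L) {
  if (n_participants < 1 || trials_per_side < 1)
    hr_stop("`n_participants` and `trials_per_side` must be >= 1",
            "headreach_invalid_argument")
  stopifnot(inherits(paralyzed_params, "sided_motion_params"),
            inherits(nonparalyzed_params, "sided_motion_params"))
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_side = as.integer(trials_per_side),
                 paralyzed_params = paralyzed_params,
                 nonparalyzed_params = nonparalyzed_params,
                 geometry = geometry, seed = seed),
            class = "cohort_spec")
}
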