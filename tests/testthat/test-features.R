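test_that("noiseless trials recover the configured end-pose peaks", {
  p <- noiseless_params("paralyzed")   # end pose 48.9 / 117.5 / 134.2 deg
  tr <- simulate_trial(arm_geometry(), p, seed = 1)
  f <- extract_features(tr)
  for (ph in c("outward", "return")) {
    row <- f[f$phase == ph, ]
    expect_lt(abs(row$peak_shoulder_flex - 48.9), 0.5)
    expect_lt(abs(row$peak_shoulder_abd - 117.5), 0.5)
    expect_lt(abs(row$peak_elbow_flex - 134.2), 0.5)
  }
  expect_true(all(f$disp_manubrium >= 0 & f$disp_occiput >= 0))
})

test_that("a zero-motion trial raises an error naming the trial", {
  mk <- lapply(forward_kinematics(arm_geometry(), 0, 0, 0),
               function(p) matrix(rep(p, each = 300), 300, 3))
  tr <- headreach:::trial_recording("still_trial", "paralyzed", "right",
                                    100, mk)
  tr$trial_id <- "still_trial"
  expect_error(extract_features(tr), regexp = "still_trial",
               class = "headreach_no_motion")
})

test_that("feature extraction is exactly reproducible for noiseless input", {
  tr <- simulate_trial(arm_geometry(), noiseless_params("non_paralyzed"),
                       seed = 3)
  expect_identical(extract_features(tr), extract_features(tr))
})

test_that("the default cohort yields one outward and one return row per trial", {
  feats <- extract_cohort_features(
    generate_cohort(cohort_spec(n_participants = 2, trials_per_side = 2,
                                seed = 5)))
  expect_equal(sum(feats$phase == "outward"), 8)
  expect_equal(sum(feats$phase == "return"), 8)
  expect_true(all(table(feats$trial_id) == 2))   # trials never averaged
})

test_that("per-frame peak velocity dominates the phase-average quotient", {
  tr <- simulate_trial(arm_geometry(), default_motion_params("paralyzed"),
                       seed = 13)
  f_peak <- extract_features(tr, feature_config(velocity_mode = "per_frame"))
  f_avg <- extract_features(tr, feature_config(velocity_mode = "phase_average"))
  for (v in c("peak_vel_shoulder_flex", "peak_vel_shoulder_abd",
              "peak_vel_elbow_flex"))
    expect_true(all(f_peak[[v]] >= f_avg[[v]] - 1e-9))
})
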