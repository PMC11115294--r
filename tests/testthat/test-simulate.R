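test_that("cohort sizes follow the design n_participants x 2 x trials", {
  expect_length(generate_cohort(cohort_spec(seed = 3)), 100)
  expect_length(generate_cohort(cohort_spec(n_participants = 2,
                                            trials_per_side = 1, seed = 3)), 4)
})

test_that("identical seeds give bitwise-identical recordings and cohorts", {
  g <- arm_geometry()
  p <- default_motion_params("paralyzed")
  t1 <- simulate_trial(g, p, seed = 99)
  t2 <- simulate_trial(g, p, seed = 99)
  expect_identical(t1, t2)

  spec <- cohort_spec(n_participants = 2, trials_per_side = 2, seed = 42)
  f1 <- extract_cohort_features(generate_cohort(spec))
  f2 <- extract_cohort_features(generate_cohort(spec))
  expect_identical(f1, f2)
})

test_that("recordings carry the required marker set at 100 Hz", {
  tr <- simulate_trial(arm_geometry(), default_motion_params("paralyzed"),
                       seed = 1)
  expect_s3_class(tr, "trial_recording")
  expect_equal(tr$sampling_rate, 100)
  expect_true(all(c("RSHO", "RELB", "RWRA", "RWRB", "RFIN", "CLAV", "C7",
                    "RBHD", "LBHD") %in% names(tr$markers)))
  lens <- vapply(tr$markers, nrow, integer(1))
  expect_length(unique(lens), 1)

  left <- simulate_trial(arm_geometry(), default_motion_params("non_paralyzed"),
                         seed = 1, limb = "left", side = "non_paralyzed")
  expect_true(all(c("LSHO", "LELB", "LFIN") %in% names(left$markers)))
})

test_that("left-limb trials are exact mirrors of right-limb trials", {
  p <- noiseless_params("paralyzed")
  r <- simulate_trial(arm_geometry(), p, seed = 5, limb = "right")
  l <- simulate_trial(arm_geometry(), p, seed = 5, limb = "left")
  expect_equal(l$markers$LELB[, 2], -r$markers$RELB[, 2])
  expect_equal(l$markers$LELB[, c(1, 3)], r$markers$RELB[, c(1, 3)])
  # mirrored trials yield identical joint-angle features
  fr <- extract_features(r)
  fl <- extract_features(l)
  expect_equal(fl$peak_shoulder_abd, fr$peak_shoulder_abd, tolerance = 1e-9)
  expect_equal(fl$peak_shoulder_flex, fr$peak_shoulder_flex, tolerance = 1e-9)
})

test_that("default cohort reproduces the configured side-dependent means", {
  feats <- extract_cohort_features(generate_cohort(cohort_spec(seed = 1)))
  out <- feats[feats$phase == "outward", ]
  expected <- list(   # per side: mean, sd of the generator defaults
    paralyzed = list(motor_time = c(2.3, 0.7),
                     peak_shoulder_flex = c(48.9, 15.4),
                     peak_shoulder_abd = c(117.5, 16.7),
                     peak_elbow_flex = c(134.2, 8.0)),
    non_paralyzed = list(motor_time = c(1.3, 0.3),
                         peak_shoulder_flex = c(42.3, 11.2),
                         peak_shoulder_abd = c(118.9, 6.2),
                         peak_elbow_flex = c(140.0, 6.1)))
  for (side in names(expected)) {
    sub <- out[out$side == side, ]
    for (v in names(expected[[side]])) {
      ms <- expected[[side]][[v]]
      se <- ms[2] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[v]]) - ms[1]), 2 * se,
                label = sprintf("%s %s mean error", side, v))
    }
  }
})

test_that("participant covariates are shared across a participant's trials", {
  trials <- generate_cohort(cohort_spec(n_participants = 3, seed = 8))
  by_pid <- split(trials, vapply(trials, `[[`, "", "participant_id"))
  for (trs in by_pid) {
    ages <- vapply(trs, function(tr) tr$metadata$age, numeric(1))
    expect_length(unique(ages), 1)
  }
})
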