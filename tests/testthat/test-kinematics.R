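test_that("segment bases are orthonormal and right-handed", {
  tr <- simulate_trial(arm_geometry(), default_motion_params("paralyzed"),
                       seed = 21)
  b <- build_segment_bases(tr)
  for (seg in c("trunk", "upper_arm", "forearm")) {
    ax <- b[[seg]]
    expect_lt(max(abs(rowSums(ax$x^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(ax$y^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(ax$z^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(ax$x * ax$y))), 1e-9)
    expect_lt(max(abs(rowSums(ax$x * ax$z))), 1e-9)
    expect_lt(max(abs(rowSums(ax$y * ax$z))), 1e-9)
  }
})

test_that("zero-pose upper-arm axis is antiparallel to the trunk vertical", {
  b <- build_segment_bases(fk_trial(0, 0, 0))
  expect_equal(rowSums(b$upper_arm$z * b$trunk$z), rep(1, 3),
               tolerance = 1e-9)   # z_ua points proximally, i.e. up
})

test_that("missing markers raise a named error", {
  tr <- simulate_trial(arm_geometry(), default_motion_params("paralyzed"),
                       seed = 1)
  tr$markers$CLAV <- NULL
  expect_error(build_segment_bases(tr), regexp = "CLAV",
               class = "headreach_missing_marker")
})

test_that("angles are invariant to vertical-axis rotation and translation", {
  p <- noiseless_params("paralyzed")
  tr <- simulate_trial(arm_geometry(), p, seed = 31)
  f0 <- extract_features(tr)
  th <- 2 * pi * 0.23
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(431, -220, 57)
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m)
    m %*% t(Rz) + matrix(shift, nrow(m), 3, byrow = TRUE))
  f1 <- extract_features(tr2)
  for (v in c("motor_time", "peak_shoulder_flex", "peak_shoulder_abd",
              "peak_elbow_flex", "peak_vel_elbow_flex"))
    expect_equal(f1[[v]], f0[[v]], tolerance = 1e-6)
})

test_that("angular velocity matches analytic rates", {
  expect_true(all(angular_velocity(rep(7, 100), 100) == 0))
  ramp <- seq(0, 90, length.out = 101)
  v <- angular_velocity(ramp, 100)
  expect_equal(v[2:100], rep(90, 99), tolerance = 1e-9)
  mj <- minimum_jerk_profile(0, 90, 1, 100)
  expect_lt(abs(max(angular_velocity(mj, 100)) - 168.75), 0.5)
  expect_error(angular_velocity(c(1, 2), 100),
               class = "headreach_invalid_argument")
})
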