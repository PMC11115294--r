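test_that("static and sub-threshold series raise no-motion errors", {
  static <- matrix(5, 200, 3)
  expect_error(detect_motion_bounds(static, 100),
               class = "headreach_no_motion")

  set.seed(4)
  # jitter whose per-frame speed stays below the threshold
  jit <- matrix(rnorm(600, 0, 0.004), 200, 3)
  v <- headreach:::marker_speed(jit, 100)
  expect_true(all(v < 5))
  expect_error(detect_motion_bounds(jit, 100, speed_eps = 5),
               class = "headreach_no_motion")
})

test_that("too-short input is rejected", {
  expect_error(detect_motion_bounds(matrix(0, 30, 3), 100),
               class = "headreach_invalid_argument")
})

test_that("noiseless simulated trials recover the configured motor time", {
  p <- noiseless_params("non_paralyzed")
  for (mt in c(1.0, 1.5, 2.5)) {
    tr <- simulate_trial(arm_geometry(), p,
                         targets = list(t_out = mt, t_ret = mt), seed = 1)
    f <- extract_features(tr)
    expect_equal(f$motor_time[f$phase == "outward"], mt, tolerance = 0.02)
    expect_equal(f$motor_time[f$phase == "return"], mt, tolerance = 0.02)
  }
})

test_that("longer configured motor time gives longer extracted motor time", {
  p <- noiseless_params("paralyzed")
  times <- c(0.9, 1.4, 2.0, 2.8)
  got <- vapply(times, function(mt) {
    tr <- simulate_trial(arm_geometry(), p,
                         targets = list(t_out = mt, t_ret = 1.5), seed = 2)
    f <- extract_features(tr)
    f$motor_time[f$phase == "outward"]
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("marker displacement is the exhaustive max-norm excursion", {
  static <- matrix(2, 50, 3)
  b <- list(onset_frame = 5, end_frame = 45)
  expect_equal(marker_displacement(static, b), 0)

  shifted <- static
  shifted[20:30, 1] <- 12    # pure 10 mm translation
  expect_equal(marker_displacement(shifted, b), 10)

  set.seed(9)
  walk <- apply(matrix(rnorm(150), 50, 3), 2, cumsum)
  ref <- walk[5, ]
  oracle <- max(vapply(5:45, function(i)
    sqrt(sum((walk[i, ] - ref)^2)), numeric(1)))
  expect_equal(marker_displacement(walk, b), oracle)
})
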