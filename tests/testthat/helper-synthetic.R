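# Shared fixtures, built in code.

# side params with all randomness and nuisance signals switched off
noiseless_params <- function(side = "paralyzed", ...) {
  p <- default_motion_params(side)
  p$motor_time_sd <- 0
  p$motor_time_return_sd <- 0
  p$peak_shoulder_flex[2] <- 0
  p$peak_shoulder_abd[2] <- 0
  p$peak_elbow_flex[2] <- 0
  p$marker_noise_sd <- 0
  p$trunk_sway_amp <- 0
  p$head_sway_amp <- 0
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  p
}

# static single-pose trial from forward kinematics (3 identical frames)
fk_trial <- function(flex, abd, elbow, geometry = arm_geometry(), nf = 3) {
  fk <- forward_kinematics(geometry, flex, abd, elbow)
  mk <- lapply(fk, function(p) matrix(rep(p, each = nf), nf, 3))
  headreach:::trial_recording("FK", "paralyzed", "right", 100, mk)
}

extract_shoulder_elbow <- function(trial) {
  b <- build_segment_bases(trial)
  sh <- shoulder_angles(b)
  el <- elbow_flexion(b)
  c(flex = sh$flex[1], abd = sh$abd[1], elbow = el[1])
}

# isotropic Gaussian blobs around simplex-vertex centres (equidistant)
simplex_blobs <- function(k, n_per, p = 4, sep = 15, sd = 1) {
  stopifnot(k <= p)
  centers <- diag(p)[seq_len(k), , drop = FALSE] * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, 0, sd), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}
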