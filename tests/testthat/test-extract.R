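test_that("LSB conversion divides by the sensitivity scale factor", {
  expect_equal(lsb_to_g(16384), 1)
  expect_equal(lsb_to_g(0), 0)
  expect_equal(lsb_to_g(8192), 0.5)
  expect_error(lsb_to_g(1, sensitivity = 0), "positive")
  expect_error(lsb_to_g(1, sensitivity = -5), "positive")
})

test_that("the low-pass filter has unit DC gain and the right roll-off", {
  fs <- 60
  expect_equal(lowpass_sway(rep(2.5, 200), fs), rep(2.5, 200))

  t <- (0:1799) / fs
  keep <- 600:1800   # past any transient
  lo <- lowpass_sway(sin(2 * pi * 0.5 * t), fs)
  expect_gte(max(abs(lo[keep])), 0.98)
  hi <- lowpass_sway(sin(2 * pi * 20 * t), fs)
  expect_lte(max(abs(hi[keep])), 0.08)

  expect_error(lowpass_sway(1:10, fs = 60, cutoff = 30), "Nyquist")
  expect_error(lowpass_sway(1:10, fs = 60, cutoff = 40), "Nyquist")
})

test_that("ground projection reproduces the direction-cosine geometry", {
  up <- project_sway(0, 0, 1, L_cm = 100)
  expect_equal(up$dx_cm, 0)
  expect_equal(up$H_cm, 100)

  side <- project_sway(1, 0, 0, L_cm = 100)
  expect_equal(side$dx_cm, -100)
  expect_equal(side$H_cm, 0)

  lean <- project_sway(0.5, 0, sqrt(3) / 2, L_cm = 100)
  expect_equal(lean$dx_cm, -50)
  expect_equal(lean$H_cm, 100 * sqrt(3) / 2, tolerance = 1e-9)

  expect_error(project_sway(c(1, 0), c(0, 0), c(0, 0), 100), "index 2")
})

test_that("projection conserves the unit sphere and the pendulum length", {
  n <- 2000
  acc <- withr::with_seed(8, matrix(rnorm(3 * n, sd = 0.5), n, 3))
  acc[, 3] <- acc[, 3] + 1
  keep <- sqrt(rowSums(acc^2)) > 1e-6
  acc <- acc[keep, ]
  sw <- project_sway(acc[, 1], acc[, 2], acc[, 3], L_cm = 91)
  expect_lt(max(abs(sw$cos_alpha^2 + sw$cos_beta^2 + sw$cos_gamma^2 - 1)),
            1e-9)
  expect_lt(max(abs((sw$dx_cm^2 + sw$dy_cm^2 + sw$H_cm^2) / 91^2 - 1)),
            1e-6)

  # scale invariance in the acceleration units
  sw2 <- project_sway(981 * acc[, 1], 981 * acc[, 2], 981 * acc[, 3], 91)
  expect_equal(sw2$dx_cm, sw$dx_cm, tolerance = 1e-12)
})

test_that("kinematics follow the first-difference definitions", {
  k <- derive_kinematics(c(0, 1, 2), fs = 60)
  expect_equal(k$velocity, c(60, 60))
  expect_equal(k$acceleration, 0)

  k2 <- derive_kinematics(c(5, 5, 6), fs = 60)
  expect_equal(k2$position, c(0, 0, 1))
  expect_equal(k2$velocity, c(0, 60))
  expect_equal(k2$acceleration, 3600)

  k3 <- derive_kinematics(rep(4.2, 50), fs = 60)
  expect_true(all(k3$position == 0) && all(k3$velocity == 0) &&
                all(k3$acceleration == 0))

  expect_error(derive_kinematics(c(1, 2), fs = 60), "insufficient")
})

test_that("velocity and acceleration match a brute-force difference loop", {
  d <- withr::with_seed(10, rnorm(50))
  fs <- 60
  k <- derive_kinematics(d, fs)
  D <- d - d[1]
  V <- numeric(49); A <- numeric(48)
  for (n in 2:50) V[n - 1] <- (D[n] - D[n - 1]) * fs
  for (n in 2:49) A[n - 1] <- (V[n] - V[n - 1]) * fs
  expect_identical(k$velocity, V)
  expect_identical(k$acceleration, A)
})

test_that("RMS features are the root mean squares and are homogeneous", {
  kin <- structure(list(position = c(3, 4), velocity = 0, acceleration = 0,
                        fs = 60), class = "sway_kinematics")
  expect_equal(rms_features(kin)$rms_position_cm, sqrt(12.5))

  zero <- derive_kinematics(rep(0, 10), 60)
  expect_true(all(unlist(rms_features(zero)) == 0))

  d <- withr::with_seed(3, rnorm(30))
  r1 <- rms_features(derive_kinematics(d, 60))
  r3 <- rms_features(derive_kinematics(3 * d, 60))
  expect_equal(unlist(r3), 3 * unlist(r1), tolerance = 1e-12)
})

test_that("feature extraction recovers the generator's targets", {
  ctrl <- simulate_cohort(n_subjects = 3, noise_sd = 0,
                          amplitude_jitter_sd = 0, bandwidth_jitter_sd = 0,
                          seed = 21)
  feats <- extract_sway_features(ctrl)
  spec <- mctsib_conditions()
  target <- ifelse(feats$direction == "ML",
                   spec$ml_rms_cm[feats$condition],
                   spec$ap_rms_cm[feats$condition])
  expect_lt(max(abs(feats$rms_position_cm / target - 1)), 0.02)

  # doubling the generator target doubles the recovered RMS
  spec2 <- mctsib_conditions(ml_rms_cm = 2 * spec$ml_rms_cm,
                             ap_rms_cm = 2 * spec$ap_rms_cm)
  feats2 <- extract_sway_features(
    simulate_cohort(n_subjects = 3, conditions = spec2, noise_sd = 0,
                    amplitude_jitter_sd = 0, bandwidth_jitter_sd = 0,
                    seed = 21))
  expect_lt(max(abs(feats2$rms_position_cm / feats$rms_position_cm - 2)),
            0.04)
})

test_that("a zero-sway recording yields all-zero features", {
  still <- mctsib_conditions(ml_rms_cm = rep(0, 4), ap_rms_cm = rep(0, 4))
  cohort <- simulate_cohort(n_subjects = 1, conditions = still, noise_sd = 0,
                            amplitude_jitter_sd = 0, bandwidth_jitter_sd = 0,
                            duration_s = 2, seed = 1)
  feats <- extract_sway_features(cohort)
  expect_true(all(abs(feats$rms_position_cm) < 1e-12))
  expect_true(all(abs(feats$rms_velocity_cms) < 1e-12))
})

test_that("feature CSV round trip preserves the table", {
  path <- withr::local_tempfile(fileext = ".csv")
  feats <- extract_sway_features(
    simulate_cohort(n_subjects = 2, duration_s = 2, seed = 2))
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(as.data.frame(back), as.data.frame(feats))
})
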