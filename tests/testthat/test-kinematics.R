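test_that("channel magnitudes are Euclidean norms in channel units", {
  rec <- imu_recording(
    acc_g = rbind(c(0, -1, 0), c(0.6, 0.8, 0), c(0, 0, 0)),
    gyro_dps = rbind(c(3, 4, 0), c(0, 0, 5), c(1, 2, 2)),
    euler_deg = matrix(0, 3, 3))
  expect_equal(as.numeric(magnitude(rec, "acc")), c(1, 1, 0))
  expect_equal(as.numeric(magnitude(rec, "gyro")), c(5, 5, 3))
  expect_equal(attr(magnitude(rec, "acc"), "unit"), "g")
  expect_error(magnitude(rec, "euler"))
})

test_that("magnitude is invariant under simultaneous rotation", {
  set.seed(41)
  for (i in 1:20) {
    v <- matrix(rnorm(30), 10, 3)
    e <- matrix(runif(3, -180, 180), 10, 3, byrow = TRUE)
    vr <- preimpact:::body_from_world(e, v)
    rec1 <- imu_recording(v, matrix(0, 10, 3), matrix(0, 10, 3))
    rec2 <- imu_recording(vr, matrix(0, 10, 3), matrix(0, 10, 3))
    expect_equal(as.numeric(magnitude(rec1, "acc")),
                 as.numeric(magnitude(rec2, "acc")), tolerance = 1e-12)
  }
})

test_that("posture angles follow the configured Euler-name mapping", {
  rec <- static_recording(50, euler = c(30, 5, -12))
  ang <- posture_angles(rec)
  expect_equal(as.numeric(ang$pitch), rep(30, 50))
  expect_equal(as.numeric(ang$roll), rep(-12, 50))
  swapped <- posture_angles(rec, mapping = c(pitch = "z", roll = "x"))
  expect_equal(as.numeric(swapped$pitch), rep(-12, 50))
  # upright standing: both angles ~0
  up <- posture_angles(static_recording(10))
  expect_equal(as.numeric(up$pitch), rep(0, 10))
})

test_that("vertical acceleration cancels gravity and recovers free fall", {
  # stationary in assorted orientations: ~0 m/s^2 at every frame
  for (e in list(c(0, 0, 0), c(45, 0, 0), c(20, 110, -35), c(-80, 30, 60))) {
    va <- vertical_acceleration(static_recording(60, euler = e))
    expect_lt(max(abs(as.numeric(va))), 1e-10)
  }
  # ideal free fall in any orientation: +9.81 downward
  va_ff <- vertical_acceleration(freefall_recording(20, euler = c(30, 40, 50)))
  expect_equal(as.numeric(va_ff), rep(9.81, 20))
  # upright sensor accelerating upward at 0.5 g: -4.905 m/s^2
  n <- 10
  rec_up <- imu_recording(matrix(rep(c(0, -1.5, 0), each = n), n, 3),
                          matrix(0, n, 3), matrix(0, n, 3))
  expect_equal(as.numeric(vertical_acceleration(rec_up)), rep(-4.905, n))
})

test_that("vertical velocity integrates, resets on stillness, and matches
           the cumulative-sum oracle with reset disabled", {
  # all-zero vertical acceleration -> all-zero velocity
  vv0 <- vertical_velocity(static_recording(100))
  expect_equal(as.numeric(vv0), rep(0, 100))

  # 0.3 s ideal free fall from rest: v = g t = 2.943 m/s
  vv_ff <- vertical_velocity(freefall_recording(31),
                             reset_policy = list(enabled = FALSE))
  expect_equal(tail(as.numeric(vv_ff), 1), 9.81 * 0.3, tolerance = 0.01)

  # 0.1 s free fall then stillness >= 0.25 s: velocity returns to 0
  acc <- rbind(matrix(0, 10, 3),
               matrix(rep(c(0, -1, 0), each = 40), 40, 3))
  rec <- imu_recording(acc, matrix(0, 50, 3), matrix(0, 50, 3))
  vv <- as.numeric(vertical_velocity(rec))
  expect_gt(vv[10], 0.8)           # built up during the fall
  expect_equal(vv[50], 0)          # clamped after the stillness window
  expect_equal(tail(vv, 10), rep(0, 10))

  # reset disabled == discrete trapezoidal integral (independent oracle)
  set.seed(99)
  recn <- static_recording(200, euler = c(10, 0, 5), noise_sd = 0.05)
  a <- as.numeric(vertical_acceleration(recn))
  oracle <- cumsum(c(0, (head(a, -1) + tail(a, -1)) / 2)) / 100
  expect_equal(as.numeric(vertical_velocity(
    recn, reset_policy = list(enabled = FALSE))), oracle, tolerance = 1e-12)
})

test_that("static recordings under simulator noise stay within 0.05 m/s", {
  spec <- simulation_spec()
  for (s in 1:3) {
    rec <- simulate_adl("D01", spec, seed = 100 + s)   # 30 s standing
    expect_lt(max(abs(as.numeric(vertical_velocity(rec)))), 0.05)
  }
  rec_lie <- simulate_adl("D17", spec, seed = 5)       # 30 s lying
  expect_lt(max(abs(as.numeric(vertical_velocity(rec_lie)))), 0.05)
})
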