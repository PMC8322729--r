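test_that("sliding windows tile the recording and drop the partial tail", {
  rec <- static_recording(100)
  expect_length(sliding_windows(rec, width = 50, stride = 50), 2L)
  expect_length(sliding_windows(rec, width = 50, stride = 10), 6L)
  expect_length(sliding_windows(static_recording(49), width = 50), 0L)
  ws <- sliding_windows(rec, width = 50, stride = 10)
  expect_equal(vapply(ws, function(w) w$start_frame, 1L),
               seq(1L, 51L, by = 10L))
  expect_equal(ws[[3]]$end_frame, 70L)
})

test_that("window statistics match their defining formulas", {
  expect_equal(zcr(c(1, 2, 3)), 1)           # mean 2, one sample above
  expect_equal(zcr(rep(4, 10)), 0)
  expect_equal(zcr(c(0, 10, 0, 10)), 2)
  expect_equal(absdiff(c(1, 2, 3)), 2 / 3)
  expect_equal(absdiff(rep(7, 5)), 0)
  expect_equal(absdiff(c(0, 10)), 5)
  expect_error(zcr(numeric(0)), "empty")
})

test_that("spectral features agree with a direct DFT oracle", {
  # constant window: DC coefficient n, all others 0
  x <- rep(1, 8)
  expect_equal(fft5(x), c(8, 0, 0, 0, 0))
  expect_equal(fft5(rep(0, 50)), rep(0, 5))
  expect_error(fft5(c(1, 2, 3, 4)), "too short")

  # pure tone at bin 1, N = 50: |X_1| = N/2, other bins ~0
  n <- 50
  tone <- cos(2 * pi * (0:(n - 1)) / n)
  expect_equal(fft5(tone), c(0, 25, 0, 0, 0), tolerance = 1e-9)

  # spectral energy: [1,1,1,1] -> 16/4; zero -> 0; Parseval identity
  expect_equal(spectral_energy(rep(1, 4)), 4)
  expect_equal(spectral_energy(rep(0, 10)), 0)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(5:80, 1))
    expect_equal(spectral_energy(x), sum(x^2), tolerance = 1e-9)
    for (k in 0:4)
      expect_equal(fft5(c(x, rep(0, max(0, 5 - length(x)))))[k + 1],
                   dft_mag_direct(c(x, rep(0, max(0, 5 - length(x)))), k),
                   tolerance = 1e-9)
  }
})

test_that("extract_features yields the frozen 40-feature layout", {
  w <- random_window()
  fv <- extract_features(w)
  expect_length(fv, 40L)
  expect_equal(anyDuplicated(names(fv)), 0L)
  expect_true(all(is.finite(fv)))
  expect_equal(names(fv)[1:11],
               paste0("accm_", c("mean", "var", "rms", "zcr", "absdiff",
                                 paste0("fft", 0:4), "se")))
  expect_equal(names(fv)[23:28],
               paste0("pitch_", c("mean", "sd", "rms", "zcr", "absdiff", "se")))

  # constant window: dispersion features vanish, mean == RMS == |constant|
  wc <- make_window(matrix(rep(c(0, -1, 0), each = 50), 50, 3),
                    matrix(2, 50, 3), matrix(30, 50, 3))
  fc <- extract_features(wc)
  expect_equal(unname(fc["accm_mean"]), 1)
  expect_equal(unname(fc["accm_rms"]), 1)
  expect_equal(unname(fc[c("accm_var", "accm_absdiff", "accm_zcr")]),
               c(0, 0, 0))
  expect_equal(unname(fc["pitch_sd"]), 0)
})

test_that("every feature matches the independent direct-formula oracle", {
  set.seed(12)
  for (i in 1:200) {
    w <- random_window()
    fv <- unname(extract_features(w))
    ov <- oracle_features(w)
    expect_equal(fv, ov, tolerance = 1e-9)
  }
})

test_that("features are translation-equivariant in time", {
  set.seed(3)
  block <- matrix(rnorm(50 * 9), 50, 9)
  long <- rbind(matrix(rnorm(40 * 9), 40, 9), block,
                matrix(rnorm(30 * 9), 30, 9))
  rec <- imu_recording(long[, 1:3], long[, 4:6], long[, 7:9])
  ws <- sliding_windows(rec, width = 50, stride = 1)
  w_at_41 <- ws[[41]]  # starts exactly at the embedded block
  direct <- make_window(block[, 1:3], block[, 4:6], block[, 7:9])
  expect_equal(extract_features(w_at_41), extract_features(direct))
})

test_that("the normaliser z-scores features and tolerates degeneracy", {
  x <- matrix(c(0, 2), 2, 1, dimnames = list(NULL, "f"))
  nz <- fit_normalizer(x)
  expect_equal(as.numeric(apply_normalizer(nz, x)), c(-1, 1))

  set.seed(5)
  m <- cbind(a = rnorm(50, 10, 3), b = runif(50), const = rep(4, 50))
  nz2 <- fit_normalizer(m)
  z <- apply_normalizer(nz2, m)
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z[, 1:2], 2, function(c) sqrt(mean(c^2)))),
               c(1, 1), tolerance = 1e-12)
  expect_equal(unname(z[, 3]), rep(0, 50))  # centred only, no division

  expect_error(fit_normalizer(m[1, , drop = FALSE]), "at least 2")
  expect_error(apply_normalizer(list(), m), "fit_normalizer")
  expect_error(apply_normalizer(nz2, m[, 1:2]), "does not match")
})
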