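test_that("the task catalogue matches the published taxonomy arithmetic", {
  cat <- task_catalogue()
  expect_equal(nrow(cat), 36L)
  expect_equal(sum(startsWith(cat$task_id, "D")), 21L)
  expect_equal(sum(startsWith(cat$task_id, "F")), 15L)
  # single-trial static tasks, five trials elsewhere
  expect_equal(cat$trials[cat$task_id %in% c("D01", "D11", "D12", "D17")],
               rep(1L, 4))
  expect_equal(sum(cat$trials), 17L * 5L + 4L * 1L + 15L * 5L)  # 164
})

test_that("generated datasets are seeded, counted and labelled correctly", {
  spec <- simulation_spec(n_subjects = 2, tasks = c("D01", "F09"),
                          trials_per_task = 1, seed = 10)
  ds <- generate_dataset(spec)
  expect_length(ds, 4L)
  expect_equal(sum(!vapply(ds, function(d) is.null(d$label), TRUE)), 2L)

  ds2 <- generate_dataset(spec)
  for (i in seq_along(ds)) {
    expect_identical(ds[[i]]$rec$acc_g, ds2[[i]]$rec$acc_g)
    expect_identical(ds[[i]]$rec$gyro_dps, ds2[[i]]$rec$gyro_dps)
  }
  # serialisation is byte-identical under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(ds2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_gt(length(f1), 0L)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # a full catalogue yields 164 files per subject
  full <- generate_dataset(simulation_spec(n_subjects = 1, seed = 3))
  expect_length(full, 164L)
})

test_that("ADL primitives have their stated signal shape", {
  spec <- simulation_spec()
  # standing: acceleration magnitude ~1 g, vertical velocity ~0
  st <- simulate_adl("D01", spec, seed = 1)
  expect_equal(mean(as.numeric(magnitude(st, "acc"))), 1, tolerance = 0.01)
  expect_lt(max(abs(as.numeric(vertical_velocity(st)))), 0.05)

  # walking: the dominant non-DC DFT bin of ACC_M sits at the gait frequency
  wk <- simulate_adl("D06", spec, seed = 2)
  am <- as.numeric(magnitude(wk, "acc"))
  n <- length(am)
  spec_mag <- Mod(stats::fft(am - mean(am)))[2:(n %/% 2)]
  f_peak <- which.max(spec_mag) / (n / wk$sample_rate_hz)
  expect_equal(f_peak, 1.9, tolerance = 0.1)

  # stumble: a transient but no sustained free fall and no detection
  stm <- simulate_adl("D10", spec, seed = 3)
  expect_false(detect(stm)$is_fall)
  expect_error(simulate_adl("D99", spec), "unknown task")
  expect_error(simulate_adl("F01", spec), "fall task")
  expect_identical(simulate_adl("D06", spec, seed = 4)$acc_g,
                   simulate_adl("D06", spec, seed = 4)$acc_g)
})

test_that("simulated falls satisfy the falling-phase kinematic envelope", {
  spec <- simulation_spec()
  tasks <- sprintf("F%02d", 1:15)
  for (i in seq_along(tasks)) {
    sim <- simulate_fall(tasks[i], spec, seed = 600 + i)
    lab <- sim$label
    expect_lt(lab$onset_frame, lab$impact_frame)
    idx <- match(lab$onset_frame, sim$rec$frame):
      match(lab$impact_frame, sim$rec$frame)
    accm <- as.numeric(magnitude(sim$rec, "acc"))[idx]
    expect_lt(min(accm), 0.6)                      # free-fall dip
    vv <- as.numeric(vertical_velocity(sim$rec))
    expect_gt(vv[idx[length(idx)]], 0.5)           # downward velocity ramp
    ang <- posture_angles(sim$rec)
    row <- task_catalogue()[task_catalogue()$task_id == tasks[i], ]
    series <- if (row$plane == "sagittal") ang$pitch else ang$roll
    expect_gte(max(abs(as.numeric(series)[idx])), 55)  # posture excursion
    # impact spike in the post-fall neighbourhood
    accm_all <- as.numeric(magnitude(sim$rec, "acc"))
    spike_win <- idx[length(idx)]:min(length(accm_all), idx[length(idx)] + 10)
    expect_gt(max(accm_all[spike_win]), 2)
  }
  expect_error(simulate_fall("D01", spec), "not a fall")
})

test_that("fall durations follow the truncated normal study condition", {
  spec <- simulation_spec()
  durs <- vapply(1:120, function(s) {
    sim <- simulate_fall(sprintf("F%02d", (s - 1) %% 15 + 1), spec,
                         seed = 5000 + s)
    (sim$label$impact_frame - sim$label$onset_frame) * 10  # ms at 100 Hz
  }, 0)
  expect_gt(mean(durs), 650)
  expect_lt(mean(durs), 850)
  expect_true(all(durs >= 300))
  expect_gt(sd(durs), 80)
})
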