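test_that("standing never fires; simulated falls fire before impact", {
  standing <- static_recording(500)
  res <- detect(standing)
  expect_false(res$is_fall)
  expect_true(is.na(res$detection_frame))

  spec <- simulation_spec()
  sim <- simulate_fall("F11", spec, seed = 7)
  res2 <- detect(sim$rec)
  expect_true(res2$is_fall)
  expect_lt(res2$detection_frame, sim$label$impact_frame)
  expect_gte(res2$detection_frame, sim$label$onset_frame)
  expect_setequal(intersect(res2$triggered_criteria, c("acc", "vv")),
                  c("acc", "vv"))

  # an unsatisfiable free-fall criterion suppresses detection
  strict <- threshold_config(acc_m_g = 1e-4)
  expect_false(detect(sim$rec, strict)$is_fall)
})

test_that("detection is monotone in each threshold direction", {
  spec <- simulation_spec()
  base <- threshold_config()
  for (s in 1:5) {
    sim <- simulate_fall(sprintf("F%02d", 2 * s), spec, seed = 300 + s)
    stopifnot(detect(sim$rec, base)$is_fall)
    relaxed <- list(
      threshold_config(acc_m_g = base$acc_m_g + 0.1),
      threshold_config(vv_ms = base$vv_ms / 2),
      threshold_config(pitch_deg = base$pitch_deg / 2),
      threshold_config(roll_deg = base$roll_deg / 2))
    for (cfg in relaxed) {
      r <- detect(sim$rec, cfg)
      expect_true(r$is_fall)
      expect_lte(r$detection_frame, detect(sim$rec, base)$detection_frame)
    }
  }
})

test_that("the detector is causal: truncation does not change the decision", {
  spec <- simulation_spec()
  sim <- simulate_fall("F13", spec, seed = 17)
  full <- detect(sim$rec)
  t_det <- match(full$detection_frame, sim$rec$frame)
  # truncating exactly at the detection frame preserves it
  res_at <- detect(truncate_recording(sim$rec, t_det))
  expect_equal(res_at$detection_frame, full$detection_frame)
  # truncating before the detection frame yields no detection
  res_before <- detect(truncate_recording(sim$rec, t_det - 5L))
  expect_false(res_before$is_fall)
})

test_that("custom combination predicates are honoured and validated", {
  spec <- simulation_spec()
  sim <- simulate_fall("F09", spec, seed = 23)
  # posture-only predicate fires earlier than the full conjunction
  posture_only <- threshold_config(combination = "pitch | roll")
  r1 <- detect(sim$rec, posture_only)
  r2 <- detect(sim$rec)
  expect_true(r1$is_fall)
  expect_lte(r1$detection_frame, r2$detection_frame)
  expect_error(detect(sim$rec, threshold_config(combination = "acc & bad")),
               "invalid combination")
  expect_error(threshold_config(acc_m_g = -1), "positive")
})

test_that("grid search equals the brute-force maximum and validates input", {
  spec <- simulation_spec(n_subjects = 2,
                          tasks = c("D01", "D06", "F07", "F11"),
                          trials_per_task = 2, seed = 77)
  ds <- generate_dataset(spec)

  grids <- list(acc_m_g = c(0.3, 0.8), pitch_deg = c(25, 70),
                roll_deg = c(25, 70), vv_ms = c(0.3, 2.0))
  gs <- grid_search_thresholds(ds, grids)

  # independent brute force: re-score every config through evaluate()
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  youden <- apply(combos, 1L, function(row) {
    cfg <- threshold_config(acc_m_g = row[["acc_m_g"]],
                            pitch_deg = row[["pitch_deg"]],
                            roll_deg = row[["roll_deg"]],
                            vv_ms = row[["vv_ms"]])
    rep <- evaluate(ds, threshold_frame_detector(cfg))
    (rep$sensitivity_pct + rep$specificity_pct) / 100 - 1
  })
  expect_equal(gs$score, max(youden), tolerance = 1e-12)

  # a single-config grid returns that config
  single <- grid_search_thresholds(ds, list(acc_m_g = 0.8))
  expect_equal(single$config$acc_m_g, 0.8)

  # defaults perfectly separate this synthetic set
  expect_equal(gs$score, 1)

  falls_only <- Filter(function(d) !is.null(d$label), ds)
  expect_error(grid_search_thresholds(falls_only, grids), "both")
  expect_error(grid_search_thresholds(ds, list(acc_m_g = numeric(0))),
               "empty grid")
})
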