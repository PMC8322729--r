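# Seeded kinematic simulator of labelled IMU recordings: 21 ADL types and
# 15 fall types following the D01-D21 / F01-F15 task taxonomy.
#
# The simulator is an idealized kinematic sketch, not a biomechanical
# model. Signals are generated top-down: an orientation trajectory (Euler
# angles) and a world-frame acceleration plan are chosen per task, then the
# body-frame accelerometer signal is derived by rotating the
# gravity-plus-motion vector into the body frame, and the gyroscope as the
# Euler-rate. This guarantees the accelerometer, gyroscope and orientation
# channels are mutually consistent, which is what the kinematics module
# assumes. Falls follow the labelled phase structure: a pre-fall segment of
# the task's preceding activity, a falling segment with a free-fall dip of
# the acceleration magnitude, a monotone downward-velocity ramp and a
# large posture excursion in the task's fall plane, an impact spike, and a
# post-fall rest.

.TASK_CATALOGUE <- local({
  adl <- data.frame(
    task_id = sprintf("D%02d", 1:21),
    description = c(
      "Stand for 30 s",
      "Stand, slowly bend the back, tie shoe lace, and get up",
      "Pick up an object from the floor",
      "Gently jump (try to reach an object)",
      "Stand, sit to the ground, wait a moment, and get up",
      "Walk normally with turn (4 m)",
      "Walk quickly with turn (4 m)",
      "Jog normally with turn (4 m)",
      "Jog quickly with turn (4 m)",
      "Stumble while walking",
      "Sit on a chair for 30 s",
      "Sit on the sofa (back inclined to the support) for 30 s",
      "Sit down to a chair normally, and get up normally",
      "Sit down to a chair quickly, and get up quickly",
      "Sit a moment, trying to get up, and collapse into a chair",
      "Stand, sit on the sofa (back inclined), and get up normally",
      "Lie on the bed for 30 s",
      "Sit a moment, lie down to the bed normally, and get up normally",
      "Sit a moment, lie down to the bed quickly, and get up quickly",
      "Walk upstairs and downstairs normally (five steps)",
      "Walk upstairs and downstairs quickly (five steps)"),
    trials = c(1L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 1L, 1L, 5L, 5L,
               5L, 5L, 1L, 5L, 5L, 5L, 5L),
    kind = c("static", "bend", "bend", "jump", "sit_ground", "gait",
             "gait", "gait", "gait", "stumble", "static", "static",
             "sit_stand", "sit_stand", "sit_stand", "sit_stand", "static",
             "lie_down", "lie_down", "gait", "gait"),
    duration_s = c(30, 12, 6, 6, 15, 8, 6, 8, 6, 8, 30, 30, 10, 8, 8,
                   12, 30, 15, 10, 10, 8),
    stringsAsFactors = FALSE)
  fall <- data.frame(
    task_id = sprintf("F%02d", 1:15),
    description = c(
      "Forward fall when trying to sit down",
      "Backward fall when trying to sit down",
      "Lateral fall when trying to sit down",
      "Forward fall when trying to get up",
      "Lateral fall when trying to get up",
      "Forward fall while sitting, caused by fainting",
      "Lateral fall while sitting, caused by fainting",
      "Backward fall while sitting, caused by fainting",
      "Vertical (forward) fall while walking caused by fainting",
      "Fall while walking, use of hands to dampen fall, caused by fainting",
      "Forward fall while walking caused by a trip",
      "Forward fall while jogging caused by a trip",
      "Forward fall while walking caused by a slip",
      "Lateral fall while walking caused by a slip",
      "Backward fall while walking caused by a slip"),
    trials = rep(5L, 15L),
    kind = "fall",
    duration_s = NA_real_,
    stringsAsFactors = FALSE)
  fall$preceding <- c("sit_down", "sit_down", "sit_down", "get_up",
                      "get_up", "sitting_faint", "sitting_faint",
                      "sitting_faint", "walk", "walk", "walk", "jog",
                      "walk", "walk", "walk")
  fall$plane <- c("sagittal", "sagittal", "frontal", "sagittal", "frontal",
                  "sagittal", "frontal", "sagittal", "sagittal", "sagittal",
                  "sagittal", "sagittal", "sagittal", "frontal", "sagittal")
  fall$direction <- c(1, -1, 1, 1, 1, 1, 1, -1, 1, 1, 1, 1, 1, 1, -1)
  adl$preceding <- NA_character_
  adl$plane <- NA_character_
  adl$direction <- NA_real_
  rbind(adl, fall)
})

#' The simulated task catalogue
#'
#' 21 ADL types (D01-D21) and 15 fall types (F01-F15) with their default
#' trial counts (static tasks D01/D11/D12/D17 one trial, all others five),
#' motion kind and nominal duration. Fall rows carry the preceding
#' activity and the fall plane (sagittal falls excite pitch, frontal falls
#' roll).
#'
#' @return A data.frame with one row per task.
#' @export
task_catalogue <- function() .TASK_CATALOGUE

task_row <- function(task_id) {
  i <- match(task_id, .TASK_CATALOGUE$task_id)
  if (is.na(i)) stop(sprintf("unknown task '%s'", task_id))
  .TASK_CATALOGUE[i, ]
}

#' Simulation specification
#'
#' Bundles the generator's study conditions. Defaults: 100 Hz sampling,
#' per-channel noise SDs of 0.01 g / 0.5 deg/s / 0.2 deg, fall durations
#' drawn from Normal(746, 150) ms truncated below at 300 ms, free-fall
#' acceleration dip to 0.15-0.40 g, impact peaks of 3-6 g, and posture
#' excursions of 60-85 deg in the fall plane.
#'
#' @param n_subjects number of simulated subjects.
#' @param tasks character vector of task IDs (default: full catalogue).
#' @param trials_per_task optional single count overriding the catalogue's
#'   per-task trial numbers.
#' @param sample_rate_hz sampling rate, default 100.
#' @param noise_sd list with `acc_g`, `gyro_dps`, `euler_deg`.
#' @param fall_params list with `duration_mean_ms`, `duration_sd_ms`,
#'   `duration_min_ms`, `dip_g` (range), `impact_peak_g` (range),
#'   `angle_excursion_deg` (range).
#' @param seed integer master seed; every stochastic draw descends from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 10L,
                            tasks = NULL,
                            trials_per_task = NULL,
                            sample_rate_hz = 100,
                            noise_sd = list(acc_g = 0.01, gyro_dps = 0.5,
                                            euler_deg = 0.2),
                            fall_params = list(duration_mean_ms = 746,
                                               duration_sd_ms = 150,
                                               duration_min_ms = 300,
                                               dip_g = c(0.15, 0.40),
                                               impact_peak_g = c(3, 6),
                                               angle_excursion_deg = c(60, 85)),
                            seed = 1L) {
  if (is.null(tasks)) tasks <- .TASK_CATALOGUE$task_id
  unknown <- setdiff(tasks, .TASK_CATALOGUE$task_id)
  if (length(unknown)) stop(sprintf("unknown tasks: %s",
                                    paste(unknown, collapse = ", ")))
  stopifnot(sample_rate_hz > 0,
            all(unlist(noise_sd) >= 0),
            fall_params$duration_mean_ms > 0,
            fall_params$duration_min_ms > 0)
  structure(list(n_subjects = as.integer(n_subjects), tasks = tasks,
                 trials_per_task = trials_per_task,
                 sample_rate_hz = sample_rate_hz, noise_sd = noise_sd,
                 fall_params = fall_params, seed = as.integer(seed)),
            class = "simulation_spec")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

gauss_bell <- function(t, centre, width) exp(-0.5 * ((t - centre) / width)^2)

# R^T w for the intrinsic Z-Y-X rotation; w is n x 3 in world coordinates.
body_from_world <- function(euler_deg, w) {
  ex <- euler_deg[, 1L] * pi / 180
  ey <- euler_deg[, 2L] * pi / 180
  ez <- euler_deg[, 3L] * pi / 180
  sa <- sin(ex); ca <- cos(ex)
  sb <- sin(ey); cb <- cos(ey)
  sc <- sin(ez); cc <- cos(ez)
  r11 <- cc * cb; r12 <- cc * sb * sa - sc * ca; r13 <- cc * sb * ca + sc * sa
  r21 <- sc * cb; r22 <- sc * sb * sa + cc * ca; r23 <- sc * sb * ca - cc * sa
  r31 <- -sb;     r32 <- cb * sa;                r33 <- cb * ca
  cbind(r11 * w[, 1L] + r21 * w[, 2L] + r31 * w[, 3L],
        r12 * w[, 1L] + r22 * w[, 2L] + r32 * w[, 3L],
        r13 * w[, 1L] + r23 * w[, 2L] + r33 * w[, 3L])
}

# Assemble a recording from a world-level motion plan. a_down_g is the true
# vertical acceleration in g (positive down); h_x/h_z are horizontal world
# components; body_acc_extra is added in the body frame (transients,
# impact spikes); gyro is the Euler rate plus any extra transient.
assemble_recording <- function(euler_deg, a_down_g, fs, noise_sd,
                               h_x = 0, h_z = 0,
                               body_acc_extra = NULL, gyro_extra = NULL,
                               meta = list()) {
  n <- nrow(euler_deg)
  w <- cbind(rep_len(h_x, n), a_down_g - 1, rep_len(h_z, n))
  acc <- body_from_world(euler_deg, w)
  if (!is.null(body_acc_extra)) acc <- acc + body_acc_extra
  gyro <- rbind(0, diff(euler_deg)) * fs
  if (!is.null(gyro_extra)) gyro <- gyro + gyro_extra
  acc <- acc + matrix(rnorm(3 * n, 0, noise_sd$acc_g), n, 3)
  gyro <- gyro + matrix(rnorm(3 * n, 0, noise_sd$gyro_dps), n, 3)
  euler <- euler_deg + matrix(rnorm(3 * n, 0, noise_sd$euler_deg), n, 3)
  imu_recording(acc_g = acc, gyro_dps = gyro, euler_deg = euler,
                subject_id = meta$subject_id %||% "S00",
                task_id = meta$task_id %||% "D01",
                trial_id = meta$trial_id %||% 1L,
                sample_rate_hz = fs)
}

# Static postures: Euler angles per task.
static_euler <- function(task_id) {
  switch(task_id,
         D01 = c(0, 0, 0),      # stand
         D11 = c(8, 0, 0),      # sit on chair
         D12 = c(-20, 0, 0),    # sofa, back inclined
         D17 = c(85, 0, 0),     # lie on bed
         c(0, 0, 0))
}

# Build the Euler trajectory for a pitch ramp 0 -> target -> 0 with holds.
ramp_hold_ramp <- function(n, fs, target_deg, t_up, t_hold, base = 0) {
  t <- seq_len(n) / fs
  total <- n / fs
  up_end <- total * 0.25
  down_start <- total * 0.65
  p <- base + target_deg * smoothstep((t - (up_end - t_up)) / t_up) -
    target_deg * smoothstep((t - down_start) / t_up)
  p
}

# Double bell: downward then upward world acceleration, zero net velocity.
transition_a_down <- function(t, centre, amp_g, width_s) {
  amp_g * gauss_bell(t, centre - width_s, width_s / 2) -
    amp_g * gauss_bell(t, centre + width_s, width_s / 2)
}

sim_adl_core <- function(task_id, spec, effects) {
  fs <- spec$sample_rate_hz
  row <- task_row(task_id)
  dur <- row$duration_s
  n <- round(dur * fs)
  t <- seq_len(n) / fs
  euler <- matrix(0, n, 3)
  a_down <- numeric(n)
  body_extra <- NULL

  kind <- row$kind
  if (kind == "static") {
    e0 <- static_euler(task_id)
    euler <- matrix(e0, n, 3, byrow = TRUE)
  } else if (kind == "bend") {
    target <- if (task_id == "D03") 70 else 60
    euler[, 1L] <- ramp_hold_ramp(n, fs, target, t_up = 1.5, t_hold = 2)
    a_down <- transition_a_down(t, dur * 0.25, 0.04, 0.4) +
      transition_a_down(t, dur * 0.70, -0.04, 0.4)
  } else if (kind == "gait") {
    f <- effects$gait_freq * switch(task_id, D06 = 1.9, D07 = 2.2,
                                    D08 = 2.6, D09 = 2.9, D20 = 1.8,
                                    D21 = 2.1, 2.0)
    amp <- effects$gait_amp * switch(task_id, D06 = 0.12, D07 = 0.16,
                                     D08 = 0.28, D09 = 0.32, D20 = 0.15,
                                     D21 = 0.20, 0.12)
    a_down <- amp * sin(2 * pi * f * t)
    h_x <- 0.4 * amp * sin(2 * pi * f * t + pi / 3)
    euler[, 1L] <- 3 * sin(2 * pi * f * t / 2)
    euler[, 3L] <- 2 * sin(2 * pi * f * t / 2 + pi / 4)
    euler[, 2L] <- 180 * smoothstep((t - dur * 0.45) / 1.0)  # the turn
    return(list(euler = euler, a_down = a_down, h_x = h_x,
                body_extra = NULL, n = n, fs = fs))
  } else if (kind == "jump") {
    flight <- 0.25
    t0 <- dur * 0.5
    crouch <- -0.35 * gauss_bell(t, t0 - 0.25, 0.08)
    in_flight <- as.numeric(t >= t0 & t < t0 + flight)
    land <- -1.8 * gauss_bell(t, t0 + flight + 0.05, 0.03)
    a_down <- crouch + in_flight * 1.0 + land
  } else if (kind %in% c("sit_stand", "sit_ground", "lie_down")) {
    quick <- task_id %in% c("D14", "D15", "D19")
    amp <- if (task_id == "D15") 0.12 else if (quick) 0.08 else 0.05
    width <- if (task_id == "D15") 0.3 else if (quick) 0.4 else 0.5
    target <- switch(kind, sit_stand = if (task_id == "D16") -20 else 10,
                     sit_ground = 15, lie_down = 85)
    t_up <- if (quick) 1.0 else 1.8
    euler[, 1L] <- ramp_hold_ramp(n, fs, target, t_up = t_up, t_hold = 2,
                                  base = if (kind == "lie_down") 8 else 0)
    a_down <- transition_a_down(t, dur * 0.25, amp, width) +
      transition_a_down(t, dur * 0.70, -amp, width)
  } else if (kind == "stumble") {
    f <- effects$gait_freq * 2.0
    amp <- effects$gait_amp * 0.12
    a_down <- amp * sin(2 * pi * f * t) + 0.15 * gauss_bell(t, dur * 0.5, 0.05)
    euler[, 1L] <- 3 * sin(2 * pi * f * t / 2)
    body_extra <- matrix(0, n, 3)
    body_extra[, 1L] <- 1.5 * gauss_bell(t, dur * 0.5, 0.03)
  }
  list(euler = euler, a_down = a_down, h_x = 0, body_extra = body_extra,
       n = n, fs = fs)
}

#' Simulate one ADL recording
#'
#' Static tasks hold a posture under sensor noise; gait tasks modulate the
#' vertical acceleration sinusoidally at the (subject-specific) step
#' frequency with a mid-trial turn; postural transitions ramp the pitch
#' angle smoothly with paired down/up acceleration pulses whose integrated
#' vertical velocity stays below the detector threshold; the stumble task
#' injects a brief acceleration transient without a sustained free-fall
#' dip.
#'
#' @param task_id ADL task ID (D01-D21).
#' @param spec a [simulation_spec()].
#' @param seed integer seed for this recording.
#' @param subject_id,trial_id metadata for the returned recording.
#' @param effects optional list of subject random effects
#'   (`gait_freq`, `gait_amp` multipliers; default 1).
#' @return An `imu_recording`.
#' @export
simulate_adl <- function(task_id, spec = simulation_spec(), seed = 1L,
                         subject_id = "S00", trial_id = 1L,
                         effects = list(gait_freq = 1, gait_amp = 1)) {
  row <- task_row(task_id)
  if (row$kind == "fall") stop(sprintf("'%s' is a fall task", task_id))
  with_seed(seed, {
    plan <- sim_adl_core(task_id, spec, effects)
    assemble_recording(plan$euler, plan$a_down, plan$fs, spec$noise_sd,
                       h_x = plan$h_x, body_acc_extra = plan$body_extra,
                       meta = list(subject_id = subject_id,
                                   task_id = task_id, trial_id = trial_id))
  })
}

#' Simulate one fall recording with its ground-truth label
#'
#' The falling segment has a duration drawn from the spec's truncated
#' normal, an acceleration-magnitude dip below 0.6 g, a monotone downward
#' vertical-velocity ramp, and a posture excursion of at least 60 deg about
#' the task's fall plane axis (pitch for sagittal falls, roll for lateral
#' falls). Fainting-from-sitting falls rotate fastest at onset (an
#' ease-out ramp); dynamically preceded falls carry a brief
#' acceleration-transient on the body y axis at onset. An impact spike of
#' 3-6 g follows the falling segment, then a post-fall rest in the final
#' orientation.
#'
#' @param task_id fall task ID (F01-F15).
#' @param spec a [simulation_spec()].
#' @param seed integer seed for this recording.
#' @param subject_id,trial_id metadata.
#' @param effects subject random effects as in [simulate_adl()].
#' @return A list with elements `rec` (`imu_recording`) and `label`
#'   ([fall_label()]).
#' @export
simulate_fall <- function(task_id, spec = simulation_spec(), seed = 1L,
                          subject_id = "S00", trial_id = 1L,
                          effects = list(gait_freq = 1, gait_amp = 1)) {
  row <- task_row(task_id)
  if (row$kind != "fall") stop(sprintf("'%s' is not a fall task", task_id))
  fp <- spec$fall_params
  fs <- spec$sample_rate_hz
  with_seed(seed, {
    # --- pre-fall segment from the preceding activity
    pre_dur <- runif(1, 2.5, 4)
    n_pre <- round(pre_dur * fs)
    t_pre <- seq_len(n_pre) / fs
    pre_euler <- matrix(0, n_pre, 3)
    pre_adown <- numeric(n_pre)
    pre_hx <- 0
    if (row$preceding %in% c("walk", "jog")) {
      f <- effects$gait_freq * if (row$preceding == "jog") 2.6 else 2.0
      amp <- effects$gait_amp * if (row$preceding == "jog") 0.28 else 0.12
      pre_adown <- amp * sin(2 * pi * f * t_pre)
      pre_hx <- 0.4 * amp * sin(2 * pi * f * t_pre + pi / 3)
      pre_euler[, 1L] <- 3 * sin(2 * pi * f * t_pre / 2)
    } else if (row$preceding == "sitting_faint") {
      pre_euler[, 1L] <- 8
    } else {  # sit_down / get_up: quiet stance with a small pitch drift
      pre_euler[, 1L] <- 5 * smoothstep(t_pre / pre_dur)
    }

    # --- falling segment
    dur_ms <- max(fp$duration_min_ms,
                  rnorm(1, fp$duration_mean_ms, fp$duration_sd_ms))
    n_fall <- max(10L, round(dur_ms / 1000 * fs))
    s <- seq_len(n_fall) / n_fall
    dip <- runif(1, fp$dip_g[1], fp$dip_g[2])
    accm_prof <- 1 - (1 - dip) * smoothstep(s / 0.3)
    excursion <- runif(1, fp$angle_excursion_deg[1],
                       fp$angle_excursion_deg[2]) * row$direction
    faint <- row$preceding == "sitting_faint"
    # unit ramp 0 -> 1; fainting falls rotate fastest at onset (ease-out),
    # dynamically preceded falls accelerate into the fall (smoothstep)
    prof01 <- if (faint) 1 - (1 - s)^2 else smoothstep((s - 0.05) / 0.85)
    base_pitch <- pre_euler[n_pre, 1L]
    fall_euler <- matrix(0, n_fall, 3)
    fall_euler[, 1L] <- base_pitch
    axis <- if (row$plane == "sagittal") 1L else 3L
    a0 <- fall_euler[1L, axis]
    fall_euler[, axis] <- a0 + (excursion - a0) * prof01
    fall_adown <- 1 - accm_prof

    # --- post-fall rest in the final orientation
    post_dur <- runif(1, 1, 2)
    n_post <- round(post_dur * fs)
    post_euler <- matrix(rep(fall_euler[n_fall, ], each = n_post), n_post, 3)
    post_adown <- numeric(n_post)

    n <- n_pre + n_fall + n_post
    euler <- rbind(pre_euler, fall_euler, post_euler)
    a_down <- c(pre_adown, fall_adown, post_adown)
    h_x <- c(rep_len(pre_hx, n_pre), numeric(n_fall + n_post))
    t_all <- seq_len(n) / fs
    onset_idx <- n_pre + 1L
    impact_idx <- n_pre + n_fall

    body_extra <- matrix(0, n, 3)
    gyro_extra <- matrix(0, n, 3)
    # impact spike just after the labelled impact moment
    peak <- runif(1, fp$impact_peak_g[1], fp$impact_peak_g[2])
    body_extra[, 2L] <- body_extra[, 2L] -
      peak * gauss_bell(t_all, (impact_idx + 1.5) / fs, 0.015)
    if (faint) {
      # rotational-rate transient at onset on the sensitive gyro axis
      gyro_extra[, axis] <- 60 * row$direction *
        gauss_bell(t_all, onset_idx / fs, 0.03)
    } else {
      # acceleration jerk at onset on the sensitive body y axis
      body_extra[, 2L] <- body_extra[, 2L] -
        runif(1, 0.5, 0.7) * gauss_bell(t_all, (onset_idx + 3) / fs, 0.025)
    }

    rec <- assemble_recording(euler, a_down, fs, spec$noise_sd,
                              h_x = h_x, body_acc_extra = body_extra,
                              gyro_extra = gyro_extra,
                              meta = list(subject_id = subject_id,
                                          task_id = task_id,
                                          trial_id = trial_id))
    list(rec = rec,
         label = fall_label(task_id = task_id, trial_id = trial_id,
                            onset_frame = rec$frame[onset_idx],
                            impact_frame = rec$frame[impact_idx],
                            description = row$description))
  })
}

sub_seed <- function(base, counter) {
  as.integer((as.numeric(base) * 7919 + counter * 104729) %% 2147483647)
}

#' Generate a full labelled dataset
#'
#' Produces per-subject, per-task, per-trial recordings with subject-level
#' random effects on gait frequency and amplitude (so subject-wise
#' splitting is meaningful). Every recording's randomness descends from a
#' counter-derived sub-seed of the spec's master seed, so datasets are
#' reproducible piecewise and in full.
#'
#' @param spec a [simulation_spec()].
#' @return A list of `list(rec = imu_recording, label = fall_label or
#'   NULL)`, ADLs first within each subject.
#' @export
generate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  out <- list()
  counter <- 0L
  for (si in seq_len(spec$n_subjects)) {
    subject_id <- sprintf("S%02d", si)
    effects <- with_seed(sub_seed(spec$seed, si * 1000003),
                         list(gait_freq = rnorm(1, 1, 0.05),
                              gait_amp = rnorm(1, 1, 0.10)))
    for (task_id in spec$tasks) {
      row <- task_row(task_id)
      n_tr <- spec$trials_per_task %||% row$trials
      for (tr in seq_len(n_tr)) {
        counter <- counter + 1L
        s <- sub_seed(spec$seed, counter)
        if (row$kind == "fall") {
          sim <- simulate_fall(task_id, spec, seed = s,
                               subject_id = subject_id, trial_id = tr,
                               effects = effects)
          out[[length(out) + 1L]] <- sim
        } else {
          rec <- simulate_adl(task_id, spec, seed = s,
                              subject_id = subject_id, trial_id = tr,
                              effects = effects)
          out[[length(out) + 1L]] <- list(rec = rec, label = NULL)
        }
      }
    }
  }
  out
}

#' Write a dataset as recording CSVs plus per-subject label tables
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels_by_subject <- list()
  for (d in dataset) {
    sub <- d$rec$subject_id
    subdir <- file.path(dir, sub)
    dir.create(subdir, showWarnings = FALSE)
    write_recording(d$rec, file.path(subdir, sprintf(
      "%s_%s_T%02d.csv", sub, d$rec$task_id, d$rec$trial_id)))
    if (!is.null(d$label))
      labels_by_subject[[sub]] <- c(labels_by_subject[[sub]], list(d$label))
  }
  for (sub in names(labels_by_subject))
    write_labels(labels_by_subject[[sub]],
                 file.path(dir, sub, sprintf("%s_labels.csv", sub)))
  invisible(dir)
}
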