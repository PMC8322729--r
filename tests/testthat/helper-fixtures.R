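# Shared fixtures and independent oracles, all built in code.

# --- constructed recordings ------------------------------------------------

# Stationary recording in a fixed orientation; acceleration is exactly the
# rotated gravity vector (no noise unless given).
static_recording <- function(n = 100, euler = c(0, 0, 0), noise_sd = 0,
                             fs = 100) {
  e <- matrix(euler, n, 3, byrow = TRUE)
  acc <- preimpact:::body_from_world(e, cbind(0, -1, 0))
  if (noise_sd > 0) acc <- acc + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
  imu_recording(acc_g = acc, gyro_dps = matrix(0, n, 3), euler_deg = e,
                sample_rate_hz = fs)
}

# Ideal free fall: measured acceleration identically zero.
freefall_recording <- function(n = 31, euler = c(0, 0, 0), fs = 100) {
  imu_recording(acc_g = matrix(0, n, 3), gyro_dps = matrix(0, n, 3),
                euler_deg = matrix(euler, n, 3, byrow = TRUE),
                sample_rate_hz = fs)
}

# Slice a recording to its first k frames (for causality-by-truncation).
truncate_recording <- function(rec, k) {
  idx <- seq_len(k)
  imu_recording(acc_g = rec$acc_g[idx, , drop = FALSE],
                gyro_dps = rec$gyro_dps[idx, , drop = FALSE],
                euler_deg = rec$euler_deg[idx, , drop = FALSE],
                time_s = rec$time_s[idx], frame = rec$frame[idx],
                subject_id = rec$subject_id, task_id = rec$task_id,
                trial_id = rec$trial_id, sample_rate_hz = rec$sample_rate_hz)
}

# A synthetic window object without going through a recording.
make_window <- function(acc, gyro, euler, fs = 100) {
  structure(list(acc_g = acc, gyro_dps = gyro, euler_deg = euler,
                 start_frame = 1L, end_frame = nrow(acc), width = nrow(acc),
                 sample_rate_hz = fs),
            class = "imu_window")
}

random_window <- function(width = 50) {
  make_window(matrix(rnorm(width * 3), width, 3),
              matrix(rnorm(width * 3, 0, 50), width, 3),
              matrix(rnorm(width * 3, 0, 30), width, 3))
}

# --- independent feature oracles (direct O(N^2) formulas) ------------------

dft_mag_direct <- function(x, k) {  # |X_k| by the definition sum
  n <- length(x)
  j <- seq_len(n) - 1
  Mod(sum(x * exp(-2i * pi * k * j / n)))
}

oracle_features <- function(w) {
  series <- list(
    accm = sqrt(rowSums(w$acc_g^2)),
    gyrm = sqrt(rowSums(w$gyro_dps^2)),
    pitch = w$euler_deg[, 1], roll = w$euler_deg[, 3],
    yaw = w$euler_deg[, 2])
  out <- c()
  for (nm in c("accm", "gyrm")) {
    x <- series[[nm]]; n <- length(x); mu <- sum(x) / n
    out <- c(out, mu, sum((x - mu)^2) / n, sqrt(sum(x^2) / n),
             sum(x > mu), sum(abs(x - mu)) / n,
             vapply(0:4, function(k) dft_mag_direct(x, k), 0),
             sum(vapply(0:(n - 1), function(k) dft_mag_direct(x, k)^2, 0)) / n)
  }
  for (nm in c("pitch", "roll", "yaw")) {
    x <- series[[nm]]; n <- length(x); mu <- sum(x) / n
    out <- c(out, mu, sqrt(sum((x - mu)^2) / n), sqrt(sum(x^2) / n),
             sum(x > mu), sum(abs(x - mu)) / n,
             sum(vapply(0:(n - 1), function(k) dft_mag_direct(x, k)^2, 0)) / n)
  }
  unname(out)
}

# --- cached simulated datasets (built once per test run) -------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Mixed ADL/fall dataset used for detector and classifier recovery checks.
recovery_dataset <- function() cached("recovery", function() {
  spec <- simulation_spec(
    n_subjects = 6,
    tasks = c("D01", "D06", "D08", "D13", "D18",
              "F06", "F07", "F11", "F13", "F14"),
    trials_per_task = 2, seed = 2026)
  generate_dataset(spec)
})

recovery_windows <- function() cached("recovery_windows", function() {
  lw <- label_windows(recovery_dataset(), max_adl_per_file = 12L)
  lw$split <- subject_split(lw$subject, test_fraction = 0.2, seed = 7)
  lw$train <- lw$subject %in% lw$split$train
  lw
})
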