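# Scalar signals feeding the threshold detector: channel magnitudes, posture
# angles, gravity-compensated vertical acceleration and its time integral.
#
# Conventions (all surfaced in arguments so they can be changed):
#  * Euler angles compose intrinsically Z-Y-X: the body-to-world rotation is
#    R = Rz(ez) %*% Ry(ey) %*% Rx(ex). The vertical component used below is
#    insensitive to the rotation about the vertical axis.
#  * The world "down" direction is +Y, so an upright stationary sensor reads
#    acceleration (0, -1, 0) g and the sensitive axis is body Y.
#  * Downward motion gives positive vertical acceleration and velocity, so
#    the 0.3 m/s detector threshold reads naturally.
#  * g = 9.81 m/s^2 exactly.

GRAVITY_MS2 <- 9.81

#' Per-frame magnitude of a 3-axis channel
#'
#' Euclidean (L2) norm of the acceleration or angular-velocity vector at
#' each frame. Acceleration magnitude (ACC_M) is ~1 g at rest and dips
#' toward 0 during free fall.
#'
#' @param rec an `imu_recording`.
#' @param channel `"acc"` (unit g) or `"gyro"` (unit deg/s).
#' @return A `scalar_series` (numeric vector with `unit` and
#'   `sample_rate_hz` attributes).
#' @export
magnitude <- function(rec, channel = c("acc", "gyro")) {
  stopifnot(inherits(rec, "imu_recording"))
  channel <- match.arg(channel)
  m <- if (channel == "acc") rec$acc_g else rec$gyro_dps
  scalar_series(sqrt(rowSums(m^2)),
                unit = if (channel == "acc") "g" else "deg/s",
                sample_rate_hz = rec$sample_rate_hz)
}

scalar_series <- function(values, unit, sample_rate_hz) {
  structure(as.numeric(values), unit = unit,
            sample_rate_hz = sample_rate_hz, class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d frames @ %g Hz, unit %s\n",
              length(x), attr(x, "sample_rate_hz"), attr(x, "unit")))
  print(utils::head(as.numeric(x)))
  invisible(x)
}

#' Posture angles (pitch and roll) of a recording
#'
#' Pitch is the rotation about the sensor X axis (sagittal-plane lean) and
#' roll the rotation about the Z axis (frontal-plane lean); both are read
#' from the stored Euler channels under a configurable name mapping, in
#' degrees. For a sensor worn upright on the low back both are ~0 when
#' standing and grow past 60 deg as the body approaches the ground.
#'
#' @param rec an `imu_recording`.
#' @param mapping named character vector assigning Euler storage axes
#'   (`"x"`, `"y"`, `"z"`) to the angle roles; default
#'   `c(pitch = "x", roll = "z", yaw = "y")`.
#' @return A list with `scalar_series` elements `pitch` and `roll` (deg).
#' @export
posture_angles <- function(rec, mapping = c(pitch = "x", roll = "z",
                                            yaw = "y")) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!all(c("pitch", "roll") %in% names(mapping)))
    stop("mapping must name 'pitch' and 'roll' axes")
  pick <- function(role) {
    ax <- match.arg(mapping[[role]], c("x", "y", "z"))
    scalar_series(rec$euler_deg[, ax], unit = "deg",
                  sample_rate_hz = rec$sample_rate_hz)
  }
  list(pitch = pick("pitch"), roll = pick("roll"))
}

# y-component of R %*% v for the intrinsic Z-Y-X rotation built from the
# per-frame Euler angles; vectorised over frames. This is the projection of
# the body-frame vector v onto the world vertical (down = +Y).
rotate_world_y <- function(euler_deg, v) {
  ex <- euler_deg[, 1L] * pi / 180
  ey <- euler_deg[, 2L] * pi / 180
  ez <- euler_deg[, 3L] * pi / 180
  sa <- sin(ex); ca <- cos(ex)
  sb <- sin(ey); cb <- cos(ey)
  sc <- sin(ez); cc <- cos(ez)
  # second row of Rz(ez) Ry(ey) Rx(ex)
  sc * cb * v[, 1L] +
    (sc * sb * sa + cc * ca) * v[, 2L] +
    (sc * sb * ca - cc * sa) * v[, 3L]
}

#' Gravity-compensated vertical acceleration
#'
#' Rotates the body-frame acceleration into the world frame using the
#' per-frame Euler angles (intrinsic Z-Y-X composition), takes the vertical
#' component and removes gravity. For a stationary sensor in any fixed
#' orientation the result is ~0; in ideal free fall (measured acceleration
#' zero) it is +9.81 m/s^2.
#'
#' @param rec an `imu_recording`.
#' @param g_ms2 standard gravity used for unit conversion, default 9.81.
#' @return A `scalar_series` in m/s^2, positive downward.
#' @export
vertical_acceleration <- function(rec, g_ms2 = GRAVITY_MS2) {
  stopifnot(inherits(rec, "imu_recording"))
  vy <- rotate_world_y(rec$euler_deg, rec$acc_g)
  scalar_series(g_ms2 * (vy + 1), unit = "m/s^2",
                sample_rate_hz = rec$sample_rate_hz)
}

#' Vertical velocity by trapezoidal integration
#'
#' Integrates [vertical_acceleration()] over time. Because an accelerometer
#' integral drifts, a stillness-triggered reset is applied by default: the
#' velocity is clamped to zero whenever the vertical acceleration has stayed
#' within `still_thresh_ms2` of zero for at least `still_frames` consecutive
#' frames. Long quiet recordings therefore hold ~0 m/s while genuine falls,
#' whose vertical acceleration is large, integrate unimpeded.
#'
#' @param rec an `imu_recording`.
#' @param reset_policy list with `enabled` (default TRUE),
#'   `still_thresh_ms2` (default 0.2 m/s^2) and `still_frames` (default 25
#'   frames, i.e. 0.25 s at 100 Hz). Pass `list(enabled = FALSE)` for the
#'   raw integral.
#' @param g_ms2 standard gravity, default 9.81.
#' @return A `scalar_series` in m/s, positive downward.
#' @export
vertical_velocity <- function(rec,
                              reset_policy = list(enabled = TRUE,
                                                  still_thresh_ms2 = 0.2,
                                                  still_frames = 25L),
                              g_ms2 = GRAVITY_MS2) {
  va <- vertical_acceleration(rec, g_ms2 = g_ms2)
  a <- as.numeric(va)
  n <- length(a)
  dt <- 1 / rec$sample_rate_hz
  v <- numeric(n)
  enabled <- isTRUE(reset_policy$enabled %||% TRUE)
  thr <- reset_policy$still_thresh_ms2 %||% 0.2
  need <- as.integer(reset_policy$still_frames %||% 25L)
  run <- if (abs(a[1L]) < thr) 1L else 0L
  if (n > 1L) {
    for (i in 2:n) {
      v[i] <- v[i - 1L] + (a[i - 1L] + a[i]) / 2 * dt
      if (enabled) {
        run <- if (abs(a[i]) < thr) run + 1L else 0L
        if (run >= need) v[i] <- 0
      }
    }
  }
  scalar_series(v, unit = "m/s", sample_rate_hz = rec$sample_rate_hz)
}
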