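# Reading/writing the 11-column IMU recording dialect and fall-label tables,
# and phase segmentation of labelled fall trials.

.REC_HEADERS <- c("TimeStamp", "FrameCounter",
                  "AccX", "AccY", "AccZ",
                  "GyrX", "GyrY", "GyrZ",
                  "EulerX", "EulerY", "EulerZ")

#' Construct an IMU recording
#'
#' One trial's 9-channel inertial time series with metadata. Acceleration is
#' in g, angular velocity in deg/s, orientation as three Euler angles in
#' degrees stored by the body axis they rotate about (X, Y, Z). Frame
#' counters are 1-based as produced by the acquisition hardware; all label
#' frames refer to these counter values.
#'
#' @param acc_g,gyro_dps,euler_deg numeric matrices with one row per frame
#'   and three columns (X, Y, Z axes).
#' @param time_s numeric vector of timestamps in seconds (non-decreasing).
#'   Default: frames at `1/sample_rate_hz` spacing starting at 0.
#' @param frame integer vector of strictly increasing frame-counter values.
#'   Default `1:n`.
#' @param subject_id,task_id,trial_id recording metadata. Task IDs follow the
#'   D01-D21 (ADL) / F01-F15 (fall) taxonomy but are not restricted to it.
#' @param sample_rate_hz sampling rate, default 100.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(acc_g, gyro_dps, euler_deg,
                          time_s = NULL, frame = NULL,
                          subject_id = "S00", task_id = "D01", trial_id = 1L,
                          sample_rate_hz = 100) {
  acc_g <- as_channel_matrix(acc_g, "acc_g")
  gyro_dps <- as_channel_matrix(gyro_dps, "gyro_dps")
  euler_deg <- as_channel_matrix(euler_deg, "euler_deg")
  n <- nrow(acc_g)
  if (n < 1L) stop("recording must contain at least one frame")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  if (nrow(gyro_dps) != n || nrow(euler_deg) != n)
    stop("all channels must have the same number of frames")
  if (is.null(frame)) frame <- seq_len(n)
  frame <- as.integer(frame)
  if (length(frame) != n) stop("'frame' length must match the channels")
  if (any(diff(frame) <= 0L))
    stop("frame counter must be strictly increasing")
  if (is.null(time_s)) time_s <- (frame - frame[1L]) / sample_rate_hz
  time_s <- as.numeric(time_s)
  if (length(time_s) != n) stop("'time_s' length must match the channels")
  if (any(diff(time_s) < 0)) stop("time_s must be non-decreasing")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         task_id = as.character(task_id),
         trial_id = as.integer(trial_id),
         sample_rate_hz = as.numeric(sample_rate_hz),
         time_s = time_s, frame = frame,
         acc_g = acc_g, gyro_dps = gyro_dps, euler_deg = euler_deg),
    class = "imu_recording")
}

as_channel_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("'%s' must have 3 columns", what))
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> subject %s task %s trial %d: %d frames @ %g Hz (%.2f s)\n",
    x$subject_id, x$task_id, x$trial_id, length(x$frame), x$sample_rate_hz,
    length(x$frame) / x$sample_rate_hz))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec an `imu_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(rec) length(rec$frame)

#' Construct a fall label
#'
#' Temporal label for one fall trial: the fall-onset frame (first frame of
#' the falling phase) and the fall-impact frame (body-ground contact), both
#' as frame-counter values of the paired recording.
#'
#' @param task_id,description,trial_id trial metadata.
#' @param onset_frame,impact_frame integer frame-counter values with
#'   `onset_frame < impact_frame`.
#' @return An object of class `fall_label`.
#' @export
fall_label <- function(task_id, trial_id, onset_frame, impact_frame,
                       description = "") {
  onset_frame <- as.integer(onset_frame)
  impact_frame <- as.integer(impact_frame)
  if (is.na(onset_frame) || is.na(impact_frame))
    stop("onset and impact frames must be integers")
  if (onset_frame >= impact_frame)
    stop(sprintf("fall onset frame (%d) must precede impact frame (%d)",
                 onset_frame, impact_frame))
  structure(
    list(task_id = as.character(task_id),
         description = as.character(description),
         trial_id = as.integer(trial_id),
         onset_frame = onset_frame, impact_frame = impact_frame),
    class = "fall_label")
}

#' @export
print.fall_label <- function(x, ...) {
  cat(sprintf("<fall_label> %s trial %d: onset frame %d, impact frame %d\n",
              x$task_id, x$trial_id, x$onset_frame, x$impact_frame))
  invisible(x)
}

#' Read an IMU recording from an 11-column CSV file
#'
#' Columns are, in order: timestamp (s), frame counter, AccX..Z (g),
#' GyrX..Z (deg/s), EulerX..Z (deg). A header row is optional; files are
#' accepted header-less by position.
#'
#' @param path path to the CSV file.
#' @param subject_id,task_id,trial_id metadata attached to the recording
#'   (not stored in the file).
#' @param sample_rate_hz sampling rate of the recording, default 100.
#' @return An `imu_recording`.
#' @export
read_recording <- function(path, subject_id = "S00", task_id = "D01",
                           trial_id = 1L, sample_rate_hz = 100) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  nf <- count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != 11L)
  if (length(bad) > 0L)
    stop(sprintf("malformed recording %s: line %d has %d columns, expected 11",
                 path, bad[1L], nf[bad[1L]]))
  dt <- data.table::fread(path, header = "auto", sep = ",",
                          colClasses = "numeric", data.table = FALSE)
  if (ncol(dt) != 11L)
    stop(sprintf("malformed recording %s: %d columns, expected 11",
                 path, ncol(dt)))
  if (nrow(dt) < 1L) stop(sprintf("recording %s has no data rows", path))
  frame <- as.integer(dt[[2L]])
  if (any(diff(frame) <= 0L))
    stop(sprintf("recording %s: frame counter not strictly increasing", path))
  imu_recording(acc_g = as.matrix(dt[, 3:5]),
                gyro_dps = as.matrix(dt[, 6:8]),
                euler_deg = as.matrix(dt[, 9:11]),
                time_s = dt[[1L]], frame = frame,
                subject_id = subject_id, task_id = task_id,
                trial_id = trial_id, sample_rate_hz = sample_rate_hz)
}

#' Write an IMU recording as an 11-column CSV file
#'
#' Emits the dialect read by [read_recording()], with the canonical header
#' row (TimeStamp, FrameCounter, AccX..Z, GyrX..Z, EulerX..Z).
#'
#' @param rec an `imu_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(rec$time_s, rec$frame,
                   rec$acc_g, rec$gyro_dps, rec$euler_deg)
  names(df) <- .REC_HEADERS
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a fall-label table
#'
#' Label tables have five or six columns: task code, description, trial ID,
#' fall-onset frame, fall-impact frame, and an optional notes column. CSV
#' and TSV are accepted; a header row is optional.
#'
#' @param path path to the label table.
#' @return A list of [fall_label()] objects (empty for an empty table).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (nrow(dt) == 0L) return(list())
  if (!ncol(dt) %in% c(5L, 6L))
    stop(sprintf("label table %s has %d columns, expected 5 or 6",
                 path, ncol(dt)))
  lapply(seq_len(nrow(dt)), function(i) {
    onset <- as.integer(dt[i, 4L])
    impact <- as.integer(dt[i, 5L])
    if (is.na(onset) || is.na(impact) || onset >= impact)
      stop(sprintf(
        "label table %s row %d: onset frame (%s) must precede impact (%s)",
        path, i, dt[i, 4L], dt[i, 5L]))
    fall_label(task_id = dt[i, 1L], description = dt[i, 2L],
               trial_id = dt[i, 3L], onset_frame = onset,
               impact_frame = impact)
  })
}

#' Write a fall-label table
#'
#' @param labels a list of [fall_label()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(
    TaskID = vapply(labels, function(l) l$task_id, ""),
    Description = vapply(labels, function(l) l$description, ""),
    TrialID = vapply(labels, function(l) l$trial_id, 1L),
    OnsetFrame = vapply(labels, function(l) l$onset_frame, 1L),
    ImpactFrame = vapply(labels, function(l) l$impact_frame, 1L))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Segment a labelled fall trial into pre-fall, falling and post-fall phases
#'
#' The falling phase spans `[onset, impact]` inclusive; pre-fall is
#' everything before onset and post-fall everything after impact. The three
#' intervals partition the recording. Training and evaluation use only the
#' pre-fall and falling phases; the post-fall phase is not considered for
#' pre-impact detection.
#'
#' @param rec an `imu_recording`.
#' @param label a `fall_label` whose frames lie within `rec`.
#' @return An object of class `phase_segmentation`: a list with elements
#'   `pre_fall`, `falling`, `post_fall`, each either `NULL` (empty) or an
#'   inclusive frame-counter interval `c(first, last)`.
#' @export
segment_phases <- function(rec, label) {
  stopifnot(inherits(rec, "imu_recording"), inherits(label, "fall_label"))
  lo <- rec$frame[1L]
  hi <- rec$frame[length(rec$frame)]
  if (label$onset_frame < lo || label$impact_frame > hi)
    stop(sprintf(
      "label frames [%d, %d] outside recording frame range [%d, %d]",
      label$onset_frame, label$impact_frame, lo, hi))
  interval <- function(a, b) if (a > b) NULL else c(a, b)
  structure(
    list(pre_fall = interval(lo, label$onset_frame - 1L),
         falling = interval(label$onset_frame, label$impact_frame),
         post_fall = interval(label$impact_frame + 1L, hi)),
    class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  fmt <- function(iv) if (is.null(iv)) "(empty)" else
    sprintf("[%d, %d]", iv[1L], iv[2L])
  cat("<phase_segmentation>",
      "pre-fall", fmt(x$pre_fall),
      "| falling", fmt(x$falling),
      "| post-fall", fmt(x$post_fall), "\n")
  invisible(x)
}
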