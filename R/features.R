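# Sliding-window extraction of the 40 hand-crafted window features and
# their z-score normalisation.
#
# Feature set (order is frozen; saved models depend on it):
#   acceleration magnitude, angular-velocity magnitude (11 features each):
#     mean, variance, RMS, ZCR, ABSDIFF, |DFT| coefficients 0-4, spectral
#     energy;
#   pitch, roll, yaw angles (6 features each):
#     mean, standard deviation, RMS, ZCR, ABSDIFF, spectral energy.
# Variance/SD are population moments (divide by N) for cross-backend
# determinism. ZCR here follows the source convention: the count of samples
# strictly above the window mean, not a sign-change count. The "first five
# FFT coefficients" are magnitudes of the unnormalised DFT including DC —
# the DC term of the acceleration magnitude carries gravity information
# that distinguishes free-fall windows.

#' Cut a recording into fixed-width sliding windows
#'
#' Windows start at offsets 0, `stride`, 2*`stride`, ... frames; a final
#' partial window is dropped. The default width of 50 frames is 0.5 s at
#' 100 Hz.
#'
#' @param rec an `imu_recording`.
#' @param width window width in frames (default 50).
#' @param stride hop between window starts in frames (default 10; use 1 for
#'   fine-grained detection timing).
#' @return A list of `imu_window` objects, each holding the 9-channel
#'   segment (`acc_g`, `gyro_dps`, `euler_deg`), `start_frame` and
#'   `end_frame` (frame-counter values), `width` and `sample_rate_hz`.
#'   Empty when the recording is shorter than `width`.
#' @export
sliding_windows <- function(rec, width = 50L, stride = 10L) {
  stopifnot(inherits(rec, "imu_recording"))
  width <- as.integer(width)
  stride <- as.integer(stride)
  if (width < 1L || stride < 1L) stop("width and stride must be >= 1")
  n <- n_frames(rec)
  if (width > n) return(list())
  starts <- seq.int(1L, n - width + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + width - 1L)
    structure(
      list(acc_g = rec$acc_g[idx, , drop = FALSE],
           gyro_dps = rec$gyro_dps[idx, , drop = FALSE],
           euler_deg = rec$euler_deg[idx, , drop = FALSE],
           start_frame = rec$frame[s],
           end_frame = rec$frame[s + width - 1L],
           width = width, sample_rate_hz = rec$sample_rate_hz),
      class = "imu_window")
  })
}

#' Count of samples above the window mean ("zero-crossing rate")
#'
#' Despite the conventional name, this statistic counts samples strictly
#' greater than the window mean.
#'
#' @param x numeric vector (non-empty).
#' @return integer count.
#' @export
zcr <- function(x) {
  if (length(x) == 0L) stop("empty window")
  sum(x > mean(x))
}

#' Mean absolute deviation from the window mean (ABSDIFF)
#'
#' @param x numeric vector (non-empty).
#' @return numeric scalar.
#' @export
absdiff <- function(x) {
  if (length(x) == 0L) stop("empty window")
  mean(abs(x - mean(x)))
}

#' First five DFT coefficient magnitudes
#'
#' Magnitudes of the unnormalised discrete Fourier transform at indices
#' 0-4 (DC included).
#'
#' @param x numeric vector of length >= 5.
#' @return numeric vector of length 5.
#' @export
fft5 <- function(x) {
  if (length(x) < 5L) stop("window too short for 5 DFT coefficients")
  Mod(stats::fft(x))[1:5]
}

#' Spectral energy of a window
#'
#' Sum of squared DFT coefficient magnitudes divided by the window length.
#' By Parseval's identity this equals the sum of squared samples.
#'
#' @param x numeric vector (non-empty).
#' @return numeric scalar.
#' @export
spectral_energy <- function(x) {
  if (length(x) == 0L) stop("empty window")
  sum(Mod(stats::fft(x))^2) / length(x)
}

pop_var <- function(x) mean((x - mean(x))^2)
rms <- function(x) sqrt(mean(x^2))

magnitude_features <- function(x, prefix) {
  v <- c(mean(x), pop_var(x), rms(x), zcr(x), absdiff(x), fft5(x),
         spectral_energy(x))
  names(v) <- paste0(prefix, "_",
                     c("mean", "var", "rms", "zcr", "absdiff",
                       paste0("fft", 0:4), "se"))
  v
}

angle_features <- function(x, prefix) {
  v <- c(mean(x), sqrt(pop_var(x)), rms(x), zcr(x), absdiff(x),
         spectral_energy(x))
  names(v) <- paste0(prefix, "_",
                     c("mean", "sd", "rms", "zcr", "absdiff", "se"))
  v
}

#' Extract the 40-feature descriptor of one window
#'
#' @param window an `imu_window` from [sliding_windows()].
#' @param mapping Euler-angle role mapping as in [posture_angles()].
#' @return Named numeric vector of length 40, in the frozen order
#'   documented above (acc magnitude, gyro magnitude, pitch, roll, yaw).
#' @export
extract_features <- function(window,
                             mapping = c(pitch = "x", roll = "z",
                                         yaw = "y")) {
  stopifnot(inherits(window, "imu_window"))
  acc_m <- sqrt(rowSums(window$acc_g^2))
  gyr_m <- sqrt(rowSums(window$gyro_dps^2))
  ang <- function(role)
    window$euler_deg[, match(mapping[[role]], c("x", "y", "z"))]
  c(magnitude_features(acc_m, "accm"),
    magnitude_features(gyr_m, "gyrm"),
    angle_features(ang("pitch"), "pitch"),
    angle_features(ang("roll"), "roll"),
    angle_features(ang("yaw"), "yaw"))
}

#' Feature matrix for a list of windows
#'
#' @param windows list of `imu_window` objects.
#' @param mapping Euler-angle role mapping as in [posture_angles()].
#' @return Numeric matrix, one row per window, 40 named columns. Zero rows
#'   for an empty window list.
#' @export
feature_matrix <- function(windows, mapping = c(pitch = "x", roll = "z",
                                                yaw = "y")) {
  if (length(windows) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = 40L))
  t(vapply(windows, extract_features, numeric(40L), mapping = mapping))
}

#' Fit a per-feature z-score normaliser
#'
#' Centre and scale are taken from the training matrix (population SD).
#' Zero-variance features are centred but not scaled.
#'
#' @param x training feature matrix (>= 2 rows).
#' @return An object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training vectors to fit")
  centre <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, centre)^2))
  scale[scale == 0] <- 1
  structure(list(centre = centre, scale = scale,
                 names = colnames(x)),
            class = "feature_normalizer")
}

#' Apply a fitted normaliser
#'
#' @param normalizer a `feature_normalizer` from [fit_normalizer()].
#' @param x feature matrix (or single vector) with the training columns.
#' @return Normalised matrix of the same shape.
#' @export
apply_normalizer <- function(normalizer, x) {
  if (!inherits(normalizer, "feature_normalizer"))
    stop("fit_normalizer() must be called before apply_normalizer()")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != length(normalizer$centre))
    stop("feature count does not match the fitted normalizer")
  sweep(sweep(x, 2L, normalizer$centre), 2L, normalizer$scale, "/")
}

#' Write a feature matrix as CSV with a header of feature names
#'
#' @param x feature matrix with column names.
#' @param path output path.
#' @param labels optional per-row labels appended as a final `label` column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path, labels = NULL) {
  df <- as.data.frame(x)
  if (!is.null(labels)) df$label <- as.character(labels)
  data.table::fwrite(df, path)
  invisible(path)
}
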