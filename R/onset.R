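# Semiautomatic fall-onset labelling: sensitive-axis selection by fall
# category and ranked local-peak candidates near the impact moment. The
# final choice among candidates remains with a human evaluator (the
# published labelling procedure involves subjective judgement); batch mode
# auto-accepts the top-ranked candidate.

#' Select the sensitive axis for onset labelling
#'
#' Falls preceded by dynamic movement (walking, jogging, sitting down,
#' getting up) show the clearest onset transient on the y axis of
#' acceleration — the axis aligned with gravity for an upright wearer.
#' Falls caused by fainting while sitting lack an early acceleration
#' change; their onset shows first as body rotation, so the angular
#' velocity axis of the fall plane is used instead: x (sagittal rotation)
#' for forward/backward falls, z (frontal rotation) for lateral falls.
#'
#' @param task_id fall task ID (F01-F15); when supplied, the preceding
#'   activity and fall plane default from the task catalogue.
#' @param preceding_activity `"dynamic"` or `"sitting_faint"`.
#' @param fall_plane `"sagittal"` or `"frontal"` (used for fainting
#'   falls).
#' @return Channel name: `"acc_y"`, `"gyro_x"` or `"gyro_z"`.
#' @export
select_sensitive_axis <- function(task_id = NULL,
                                  preceding_activity = NULL,
                                  fall_plane = NULL) {
  if (!is.null(task_id)) {
    row <- task_row(task_id)
    if (row$kind != "fall")
      stop(sprintf("'%s' is not a fall task", task_id))
    if (is.null(preceding_activity))
      preceding_activity <- if (row$preceding == "sitting_faint")
        "sitting_faint" else "dynamic"
    if (is.null(fall_plane)) fall_plane <- row$plane
  }
  if (is.null(preceding_activity))
    stop("need a task_id or an explicit preceding_activity")
  preceding_activity <- match.arg(preceding_activity,
                                  c("dynamic", "sitting_faint"))
  if (preceding_activity == "dynamic") return("acc_y")
  fall_plane <- match.arg(fall_plane, c("sagittal", "frontal"))
  if (fall_plane == "sagittal") "gyro_x" else "gyro_z"
}

channel_signal <- function(rec, axis) {
  parts <- strsplit(axis, "_", fixed = TRUE)[[1L]]
  m <- switch(parts[1L], acc = rec$acc_g, gyro = rec$gyro_dps,
              euler = rec$euler_deg,
              stop(sprintf("unknown channel '%s'", axis)))
  m[, parts[2L]]
}

# Topographic prominence of each local maximum of x (indices in `peaks`):
# on each side walk to the nearest strictly higher sample (or the segment
# edge) and take the minimum in between; the reference level is the higher
# of the two minima.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- min(x[(if (length(higher_l)) max(higher_l) + 1L else 1L):p])
    right <- x[p:length(x)]
    higher_r <- which(right > h)
    rmin <- min(x[p:(if (length(higher_r)) p + min(higher_r) - 2L
                     else length(x))])
    h - max(lmin, rmin)
  }, numeric(1L))
}

#' Ranked fall-onset candidates
#'
#' Finds local maxima of the absolute sensitive-axis signal within a
#' search window ending at (and excluding) the impact frame, ranks them by
#' topographic prominence (ties broken by earlier frame) and returns at
#' most `k` candidates. The default 1.5 s window covers the typical fall
#' duration (mean about 746 ms) with margin.
#'
#' @param rec an `imu_recording` of a fall trial.
#' @param axis sensitive channel name from [select_sensitive_axis()].
#' @param impact_frame labelled impact frame (frame-counter value inside
#'   the recording).
#' @param search_window_s window length before impact, default 1.5 s.
#' @param min_prominence minimum prominence in channel units, default 0.1.
#' @param k maximum number of candidates, default 5.
#' @return data.frame with columns `frame`, `axis`, `prominence`, `rank`
#'   (possibly zero rows). All candidate frames precede `impact_frame`.
#' @export
onset_candidates <- function(rec, axis, impact_frame,
                             search_window_s = 1.5, min_prominence = 0.1,
                             k = 5L) {
  stopifnot(inherits(rec, "imu_recording"))
  imp_idx <- match(as.integer(impact_frame), rec$frame)
  if (is.na(imp_idx)) stop("impact_frame not inside the recording")
  lo <- max(1L, imp_idx - as.integer(round(search_window_s *
                                             rec$sample_rate_hz)))
  hi <- imp_idx - 1L
  if (hi < lo) stop("empty search window before the impact frame")
  x <- abs(channel_signal(rec, axis))[lo:hi]
  n <- length(x)
  empty <- data.frame(frame = integer(0), axis = character(0),
                      prominence = numeric(0), rank = integer(0))
  if (n < 3L) return(empty)
  peaks <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                   x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(peaks) == 0L) return(empty)
  prom <- peak_prominence(x, peaks)
  keep <- prom >= min_prominence
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) == 0L) return(empty)
  ord <- order(-prom, peaks)
  take <- head(ord, k)
  data.frame(frame = rec$frame[lo + peaks[take] - 1L],
             axis = axis,
             prominence = prom[take],
             rank = seq_along(take))
}

#' Batch onset labelling of simulated or recorded fall trials
#'
#' For every fall recording, selects the sensitive axis from its task ID,
#' computes ranked onset candidates relative to the given impact frame
#' and auto-accepts the top-ranked candidate, emitting a label table row.
#' Interactive confirmation of a lower-ranked candidate is the caller's
#' responsibility (the procedure is semiautomatic by design).
#'
#' @param recs list of `imu_recording`s of fall trials.
#' @param impact_frames integer vector of labelled impact frames, one per
#'   recording.
#' @param ... passed to [onset_candidates()].
#' @return A list of [fall_label()]s (recordings with no candidate are
#'   skipped with a warning).
#' @export
label_onsets <- function(recs, impact_frames, ...) {
  stopifnot(length(recs) == length(impact_frames))
  out <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    axis <- select_sensitive_axis(task_id = rec$task_id)
    cand <- onset_candidates(rec, axis, impact_frames[i], ...)
    if (nrow(cand) == 0L) {
      warning(sprintf("no onset candidate for %s %s trial %d",
                      rec$subject_id, rec$task_id, rec$trial_id))
      next
    }
    out[[length(out) + 1L]] <-
      fall_label(task_id = rec$task_id, trial_id = rec$trial_id,
                 onset_frame = cand$frame[1L],
                 impact_frame = impact_frames[i],
                 description = task_row(rec$task_id)$description)
  }
  out
}
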