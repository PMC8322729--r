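# File-level scoring: pre-impact decision rule, confusion counts,
# sensitivity/specificity, lead-time statistics and subject-wise splits.

#' Confusion counts over files
#'
#' @param tp,fn,tn,fp non-negative integers. `tp + fn` is the number of
#'   fall files, `tn + fp` the number of ADL files.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d FN %d TN %d FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' File-level decision from time-ordered positive frames
#'
#' A fall file counts as detected (TP) only when some positive decision
#' occurs at or before the labelled impact frame — that is the defining
#' property of pre-impact detection; detections after impact count as
#' misses. An ADL file with any positive decision anywhere is a false
#' positive.
#'
#' @param positive_frames integer frame-counter values at which the
#'   detector emitted a positive decision (possibly empty), in time order.
#' @param label a [fall_label()] for fall files, `NULL` for ADL files.
#' @return list with `decision` (`"fall"`/`"adl"`) and `detection_frame`
#'   (first counting positive frame, or `NA`).
#' @export
classify_file <- function(positive_frames, label = NULL) {
  positive_frames <- as.integer(positive_frames)
  if (is.null(label)) {
    if (length(positive_frames) == 0L)
      return(list(decision = "adl", detection_frame = NA_integer_))
    return(list(decision = "fall", detection_frame = positive_frames[1L]))
  }
  pre <- positive_frames[positive_frames <= label$impact_frame]
  if (length(pre) == 0L)
    return(list(decision = "adl", detection_frame = NA_integer_))
  list(decision = "fall", detection_frame = pre[1L])
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = 100 * TP / (TP + FN); specificity = 100 * TN / (TN + FP).
#' Values are carried at full precision; rounding to two decimals is a
#' presentation choice (see `print`).
#'
#' @param counts a [confusion_counts()] (or the four counts).
#' @return list with `sensitivity_pct` and `specificity_pct`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0L)
    stop("sensitivity undefined: no fall files")
  if (counts$tn + counts$fp == 0L)
    stop("specificity undefined: no ADL files")
  list(sensitivity_pct = 100 * counts$tp / (counts$tp + counts$fn),
       specificity_pct = 100 * counts$tn / (counts$tn + counts$fp))
}

#' Detection lead time in milliseconds
#'
#' The interval between the detection moment and the impact moment — the
#' budget available to deploy protection (e.g. inflate an airbag) before
#' body-ground contact.
#'
#' @param detection_frame,impact_frame frame-counter values with
#'   `detection_frame <= impact_frame`.
#' @param sample_rate_hz sampling rate.
#' @return lead time in ms (0 for detection exactly at impact).
#' @export
lead_time_ms <- function(detection_frame, impact_frame, sample_rate_hz = 100) {
  if (any(detection_frame > impact_frame))
    stop("detection after impact: caller must filter to pre-impact detections")
  (impact_frame - detection_frame) / sample_rate_hz * 1000
}

#' Subject-wise train/test split
#'
#' Partitions subjects (not files) so no individual contributes to both
#' sets. With 32 subjects and the default test fraction 0.2 the split is
#' 26 training / 6 test subjects.
#'
#' @param subject_ids character vector of (possibly repeated) subject IDs.
#' @param test_fraction fraction of subjects assigned to the test set,
#'   in (0, 1); default 0.2.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with character vectors `train` and `test`.
#' @export
subject_split <- function(subject_ids, test_fraction = 0.2, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < 2L) stop("need at least 2 subjects to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- max(1L, min(length(ids) - 1L, round(length(ids) * test_fraction)))
  test <- with_seed(seed, sort(sample(ids, n_test)))
  list(train = setdiff(ids, test), test = test)
}

#' Threshold detector as a frame-decision function
#'
#' @param cfg a [threshold_config()].
#' @return A function mapping an `imu_recording` to the integer vector of
#'   frames at which the detector fires (all frames satisfying the
#'   predicate; the first is the detection moment).
#' @export
threshold_frame_detector <- function(cfg = threshold_config()) {
  force(cfg)
  function(rec) {
    sig <- detector_signals(rec, cfg$reset_policy)
    sig$frame[eval_combination(sig, cfg)]
  }
}

#' Window classifier as a frame-decision function
#'
#' Wraps a trained `fall_svm` or `convlstm` into a per-recording decision
#' function: windows are cut at the given stride, classified, and each
#' fall-positive window contributes a decision at its final frame (the
#' causal choice for a streaming detector: the decision time is the moment
#' the window completes).
#'
#' @param model trained classifier.
#' @param normalizer the training `feature_normalizer` (required for
#'   `fall_svm`, ignored for `convlstm`).
#' @param width,stride window geometry; stride 5 gives 50 ms decision
#'   granularity at 100 Hz.
#' @param decision_frame `"end"` (default) or `"start"`: which window
#'   frame timestamps the decision.
#' @return A function mapping an `imu_recording` to positive decision
#'   frames.
#' @export
window_frame_detector <- function(model, normalizer = NULL, width = 50L,
                                  stride = 5L,
                                  decision_frame = c("end", "start")) {
  decision_frame <- match.arg(decision_frame)
  force(model); force(normalizer)
  function(rec) {
    ws <- sliding_windows(rec, width = width, stride = stride)
    if (length(ws) == 0L) return(integer(0))
    pred <- if (inherits(model, "fall_svm")) {
      fm <- feature_matrix(ws)
      predict_windows(model, apply_normalizer(normalizer, fm))
    } else {
      predict_windows(model, windows_to_array(ws))
    }
    at <- if (decision_frame == "end")
      vapply(ws, function(w) w$end_frame, 1L)
    else vapply(ws, function(w) w$start_frame, 1L)
    at[pred == "fall"]
  }
}

#' Evaluate a detector file-wise over a labelled dataset
#'
#' Runs the detector on every recording, aggregates decisions with the
#' pre-impact rule of [classify_file()], and reports confusion counts,
#' sensitivity, specificity and the lead-time distribution over true
#' positives.
#'
#' @param dataset list of `list(rec, label)`; `label = NULL` marks ADL
#'   files. Both classes must be present.
#' @param detector a function `imu_recording -> integer vector of positive
#'   frames`, e.g. [threshold_frame_detector()] or
#'   [window_frame_detector()].
#' @return An object of class `evaluation_report`.
#' @export
evaluate <- function(dataset, detector) {
  tp <- fn <- tn <- fp <- 0L
  leads <- numeric(0)
  for (d in dataset) {
    res <- classify_file(detector(d$rec), d$label)
    if (is.null(d$label)) {
      if (res$decision == "fall") fp <- fp + 1L else tn <- tn + 1L
    } else if (res$decision == "fall") {
      tp <- tp + 1L
      leads <- c(leads, lead_time_ms(res$detection_frame,
                                     d$label$impact_frame,
                                     d$rec$sample_rate_hz))
    } else fn <- fn + 1L
  }
  counts <- confusion_counts(tp, fn, tn, fp)
  metrics <- confusion_metrics(counts)
  structure(list(counts = counts,
                 sensitivity_pct = metrics$sensitivity_pct,
                 specificity_pct = metrics$specificity_pct,
                 lead_times_ms = leads,
                 lead_time_mean_ms = if (length(leads)) mean(leads) else NA_real_,
                 lead_time_sd_ms = if (length(leads) > 1L) sd(leads) else NA_real_),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  c_ <- x$counts
  cat("File-level evaluation\n")
  cat(sprintf("  %-22s %s\n", "FN", sprintf("%d/%d", c_$fn, c_$tp + c_$fn)))
  cat(sprintf("  %-22s %s\n", "FP", sprintf("%d/%d", c_$fp, c_$tn + c_$fp)))
  cat(sprintf("  %-22s %.2f\n", "Sensitivity (%)", x$sensitivity_pct))
  cat(sprintf("  %-22s %.2f\n", "Specificity (%)", x$specificity_pct))
  if (length(x$lead_times_ms))
    cat(sprintf("  %-22s %.0f +- %.0f\n", "Lead time (ms)",
                x$lead_time_mean_ms, x$lead_time_sd_ms))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(schema = "preimpact/evaluation_report/v1",
            counts = report$counts[c("tp", "fn", "tn", "fp")],
            sensitivity_pct = report$sensitivity_pct,
            specificity_pct = report$specificity_pct,
            lead_time_mean_ms = report$lead_time_mean_ms,
            lead_time_sd_ms = report$lead_time_sd_ms,
            lead_times_ms = report$lead_times_ms)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
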