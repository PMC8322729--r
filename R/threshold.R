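# Threshold-based pre-impact fall detector and grid-search calibration.
#
# Four criteria are evaluated per frame: acceleration magnitude at or below
# a free-fall threshold, vertical velocity at or above a descent threshold,
# and posture (|pitch| or |roll|) at or above a lean threshold. The default
# combination is conjunctive: free-fall dip AND downward velocity AND
# posture deviation. The boolean combination is configurable.

#' Threshold detector configuration
#'
#' Default threshold values are 0.8 g (acceleration magnitude, at or
#' below), 25 deg (pitch), 25 deg (roll) and 0.3 m/s (vertical velocity, at
#' or above) — the operating point found by grid search in the benchmark
#' study this detector family comes from.
#'
#' @param acc_m_g free-fall threshold on acceleration magnitude (g); fires
#'   when ACC_M <= `acc_m_g`.
#' @param pitch_deg,roll_deg posture thresholds (deg); fire when the
#'   absolute angle >= the threshold.
#' @param vv_ms vertical-velocity threshold (m/s, positive downward); fires
#'   when VV >= `vv_ms`.
#' @param combination character predicate over the criterion flags `acc`,
#'   `vv`, `pitch`, `roll` combined with `&`, `|`, `!` and parentheses.
#' @param reset_policy passed to [vertical_velocity()].
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(acc_m_g = 0.8, pitch_deg = 25, roll_deg = 25,
                             vv_ms = 0.3,
                             combination = "acc & vv & (pitch | roll)",
                             reset_policy = NULL) {
  vals <- c(acc_m_g = acc_m_g, pitch_deg = pitch_deg,
            roll_deg = roll_deg, vv_ms = vv_ms)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive numbers")
  structure(list(acc_m_g = acc_m_g, pitch_deg = pitch_deg,
                 roll_deg = roll_deg, vv_ms = vv_ms,
                 combination = combination,
                 reset_policy = reset_policy),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(
    "<threshold_config> ACC_M <= %g g, |pitch| >= %g deg, |roll| >= %g deg, VV >= %g m/s\n  combination: %s\n",
    x$acc_m_g, x$pitch_deg, x$roll_deg, x$vv_ms, x$combination))
  invisible(x)
}

# Per-recording detector signals, computed once so grid search does not
# re-integrate velocity for every candidate configuration.
detector_signals <- function(rec, reset_policy = NULL) {
  ang <- posture_angles(rec)
  vv_args <- list(rec = rec)
  if (!is.null(reset_policy)) vv_args$reset_policy <- reset_policy
  list(acc_m = as.numeric(magnitude(rec, "acc")),
       vv = as.numeric(do.call(vertical_velocity, vv_args)),
       pitch = as.numeric(ang$pitch), roll = as.numeric(ang$roll),
       frame = rec$frame)
}

eval_combination <- function(sig, cfg) {
  flags <- list(acc = sig$acc_m <= cfg$acc_m_g,
                vv = sig$vv >= cfg$vv_ms,
                pitch = abs(sig$pitch) >= cfg$pitch_deg,
                roll = abs(sig$roll) >= cfg$roll_deg)
  expr <- parse(text = cfg$combination)[[1L]]
  ok <- all(all.names(expr) %in% c("&", "|", "!", "(", "&&", "||",
                                   "acc", "vv", "pitch", "roll"))
  if (!ok) stop(sprintf("invalid combination predicate: %s", cfg$combination))
  fire <- eval(expr, envir = flags, enclos = baseenv())
  if (!is.logical(fire) || length(fire) != length(sig$acc_m))
    stop("combination predicate must yield one boolean per frame")
  fire
}

#' Run the threshold detector on one recording
#'
#' Scans frames in time order and fires at the first frame where the
#' combination predicate holds. The decision at frame t uses no samples
#' after t, so the detector is causal and suitable for streaming use.
#'
#' @param rec an `imu_recording`.
#' @param cfg a [threshold_config()].
#' @return An object of class `detection_result`: list with `is_fall`,
#'   `detection_frame` (frame-counter value, or `NA` when no detection) and
#'   `triggered_criteria` (names of the criteria true at the firing frame).
#' @export
detect <- function(rec, cfg = threshold_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cfg, "threshold_config"))
  sig <- detector_signals(rec, cfg$reset_policy)
  fire <- eval_combination(sig, cfg)
  idx <- which(fire)
  if (length(idx) == 0L)
    return(structure(list(is_fall = FALSE, detection_frame = NA_integer_,
                          triggered_criteria = character(0)),
                     class = "detection_result"))
  i <- idx[1L]
  crit <- c(acc = sig$acc_m[i] <= cfg$acc_m_g,
            vv = sig$vv[i] >= cfg$vv_ms,
            pitch = abs(sig$pitch[i]) >= cfg$pitch_deg,
            roll = abs(sig$roll[i]) >= cfg$roll_deg)
  structure(list(is_fall = TRUE, detection_frame = sig$frame[i],
                 triggered_criteria = names(crit)[crit]),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$is_fall)
    cat(sprintf("<detection_result> fall detected at frame %d (%s)\n",
                x$detection_frame,
                paste(x$triggered_criteria, collapse = ", ")))
  else cat("<detection_result> no fall detected\n")
  invisible(x)
}

# Score one configuration against precomputed signals. Fall files count as
# detected only when the first firing frame is at or before the labelled
# impact frame; ADL files count as false positives on any firing.
score_config <- function(signals, labels, cfg) {
  tp <- fn <- tn <- fp <- 0L
  leads <- numeric(0)
  for (i in seq_along(signals)) {
    sig <- signals[[i]]
    lab <- labels[[i]]
    fire <- eval_combination(sig, cfg)
    idx <- which(fire)
    first <- if (length(idx)) sig$frame[idx[1L]] else NA_integer_
    if (is.null(lab)) {
      if (is.na(first)) tn <- tn + 1L else fp <- fp + 1L
    } else {
      if (!is.na(first) && first <= lab$impact_frame) {
        tp <- tp + 1L
        leads <- c(leads, lab$impact_frame - first)
      } else fn <- fn + 1L
    }
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(youden = sens + spec - 1, sensitivity = sens, specificity = spec,
       mean_lead_frames = if (length(leads)) mean(leads) else 0)
}

#' Grid-search calibration of the threshold detector
#'
#' Exhaustively evaluates the Cartesian product of the candidate threshold
#' values, scoring each configuration file-wise on the dataset (default
#' objective: Youden index, sensitivity + specificity - 1, with only
#' pre-impact detections counting as true positives). Ties are broken by
#' larger mean lead time, then by lexicographic order of the grid.
#'
#' @param dataset list of `list(rec = imu_recording, label = fall_label or
#'   NULL)`; must contain both fall and ADL recordings.
#' @param grids named list of candidate values for `acc_m_g`, `pitch_deg`,
#'   `roll_deg`, `vv_ms` (each defaults to the single default value).
#' @param objective objective name; `"youden"` is currently implemented.
#' @param combination predicate passed to [threshold_config()].
#' @param reset_policy passed to [vertical_velocity()].
#' @return list with `config` (best [threshold_config()]) and `score`.
#' @export
grid_search_thresholds <- function(dataset, grids = list(),
                                   objective = "youden",
                                   combination = "acc & vv & (pitch | roll)",
                                   reset_policy = NULL) {
  objective <- match.arg(objective, "youden")
  defaults <- list(acc_m_g = 0.8, pitch_deg = 25, roll_deg = 25, vv_ms = 0.3)
  for (nm in names(grids)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown grid dimension '%s'", nm))
    if (length(grids[[nm]]) == 0L)
      stop(sprintf("empty grid for '%s'", nm))
  }
  grid <- utils::modifyList(defaults, grids[names(grids)])
  labels <- lapply(dataset, function(d) d$label)
  is_fall <- !vapply(labels, is.null, TRUE)
  if (!any(is_fall) || all(is_fall))
    stop("dataset must contain both fall and ADL recordings")
  signals <- lapply(dataset, function(d)
    detector_signals(d$rec, reset_policy))
  combos <- expand.grid(vv_ms = grid$vv_ms, roll_deg = grid$roll_deg,
                        pitch_deg = grid$pitch_deg, acc_m_g = grid$acc_m_g,
                        KEEP.OUT.ATTRS = FALSE)
  # reorder so acc_m_g varies slowest: lexicographic in the documented order
  combos <- combos[, c("acc_m_g", "pitch_deg", "roll_deg", "vv_ms")]
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    cfg <- threshold_config(acc_m_g = combos$acc_m_g[r],
                            pitch_deg = combos$pitch_deg[r],
                            roll_deg = combos$roll_deg[r],
                            vv_ms = combos$vv_ms[r],
                            combination = combination,
                            reset_policy = reset_policy)
    sc <- score_config(signals, labels, cfg)
    better <- is.null(best) || sc$youden > best$score$youden ||
      (sc$youden == best$score$youden &&
         sc$mean_lead_frames > best$score$mean_lead_frames)
    if (better) best <- list(config = cfg, score = sc)
  }
  list(config = best$config, score = best$score$youden,
       sensitivity = best$score$sensitivity,
       specificity = best$score$specificity)
}
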