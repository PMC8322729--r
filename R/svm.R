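# Window labelling and the SVM classification pipeline.

#' Build a labelled window set from a dataset
#'
#' Windows are cut from every recording and labelled by the pre-impact
#' rule: a window is "fall" iff its last frame lies inside the falling
#' phase `[onset, impact]`; windows ending before onset are "adl"; windows
#' of fall trials extending past the impact frame are discarded (the
#' post-fall phase is not considered). Long ADL recordings can contribute
#' at most `max_adl_per_file` windows (evenly thinned) so static 30 s
#' trials do not swamp the training set.
#'
#' @param dataset list of `list(rec, label)` as from [generate_dataset()].
#' @param width,stride window geometry in frames (defaults 50 / 10).
#' @param max_adl_per_file cap on ADL windows kept per recording
#'   (default 20; `Inf` keeps all).
#' @return A list with `windows` (list of `imu_window`), `labels` (factor
#'   with levels `adl`, `fall`), `subject` (character vector) and
#'   `file` (integer index of the source recording in `dataset`).
#' @export
label_windows <- function(dataset, width = 50L, stride = 10L,
                          max_adl_per_file = 20L) {
  windows <- list()
  labels <- character(0)
  subject <- character(0)
  file <- integer(0)
  for (i in seq_along(dataset)) {
    d <- dataset[[i]]
    ws <- sliding_windows(d$rec, width = width, stride = stride)
    if (length(ws) == 0L) next
    if (is.null(d$label)) {
      lab <- rep("adl", length(ws))
    } else {
      ends <- vapply(ws, function(w) w$end_frame, 1L)
      keep <- ends <= d$label$impact_frame
      ws <- ws[keep]
      ends <- ends[keep]
      lab <- ifelse(ends >= d$label$onset_frame, "fall", "adl")
    }
    adl_idx <- which(lab == "adl")
    if (length(adl_idx) > max_adl_per_file) {
      keep_adl <- adl_idx[unique(round(seq(1L, length(adl_idx),
                                           length.out = max_adl_per_file)))]
      sel <- sort(c(keep_adl, which(lab == "fall")))
      ws <- ws[sel]
      lab <- lab[sel]
    }
    windows <- c(windows, ws)
    labels <- c(labels, lab)
    subject <- c(subject, rep(d$rec$subject_id, length(ws)))
    file <- c(file, rep(i, length(ws)))
  }
  list(windows = windows,
       labels = factor(labels, levels = c("adl", "fall")),
       subject = subject, file = file)
}

#' Train the SVM window classifier
#'
#' RBF-kernel support vector machine over normalised 40-feature vectors,
#' with class weights inversely proportional to class frequency. Features
#' must already be normalised (see [fit_normalizer()]); the model stores
#' the expected feature order.
#'
#' @param x normalised feature matrix (one row per window).
#' @param y factor of window labels with levels `adl`, `fall`.
#' @param cost SVM cost parameter C, default 1.
#' @param gamma RBF width; default `1/ncol(x)` (libsvm's default).
#' @param seed seed for the backend (libsvm training is deterministic for
#'   fixed inputs; the seed guards probability fitting if enabled).
#' @return An object of class `fall_svm`.
#' @export
train_svm <- function(x, y, cost = 1, gamma = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty feature set")
  y <- factor(y, levels = c("adl", "fall"))
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  if (nrow(x) != length(y)) stop("feature rows and labels differ in length")
  tab <- table(y)
  cw <- as.numeric(sum(tab) / (2 * tab))
  names(cw) <- names(tab)
  fit <- with_seed(seed,
                   e1071::svm(x, y, kernel = "radial", cost = cost,
                              gamma = gamma %||% (1 / ncol(x)),
                              class.weights = cw, scale = FALSE))
  structure(list(fit = fit, feature_names = colnames(x)),
            class = "fall_svm")
}

#' Predict window labels
#'
#' Order-preserving per-window prediction for either classifier family:
#' a `fall_svm` consumes normalised 40-feature rows, a `convlstm` consumes
#' raw 9-channel window arrays.
#'
#' @param model a `fall_svm` or `convlstm` model.
#' @param x for `fall_svm`: a feature matrix; for `convlstm`: an array
#'   `n x width x 9` (or a list of `imu_window`s, see [windows_to_array()]).
#' @return Factor of labels (`adl`/`fall`), one per window; empty input
#'   gives an empty factor.
#' @export
predict_windows <- function(model, x) UseMethod("predict_windows")

#' @export
predict_windows.fall_svm <- function(model, x) {
  if (is.null(dim(x)) && length(x) == 0L ||
      (!is.null(dim(x)) && nrow(x) == 0L))
    return(factor(character(0), levels = c("adl", "fall")))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names))
    stop(sprintf("model expects %d features, got %d",
                 length(model$feature_names), ncol(x)))
  stats::predict(model$fit, x)
}

#' Save / load a trained model archive
#'
#' Stores the model together with its normaliser and feature order so a
#' loaded model can be applied to freshly extracted windows.
#'
#' @param model a trained classifier.
#' @param normalizer the `feature_normalizer` used at training (or NULL).
#' @param path archive path.
#' @return `path` invisibly for save; the archive list for load.
#' @export
save_model <- function(model, path, normalizer = NULL) {
  saveRDS(list(model = model, normalizer = normalizer,
               package_version = as.character(utils::packageVersion("preimpact"))),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
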