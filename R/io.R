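# Plain-text I/O: one-column CSV signals, JSON for beats, annotations,
# models and metrics.

#' Read a one-column CSV voltage signal
#'
#' @param path CSV file with a single `voltage` column (header optional).
#' @param fs Sampling frequency in Hz.
#' @return An [ecg_signal()].
#' @export
read_signal_csv <- function(path, fs) {
  if (!file.exists(path)) stop_input("signal file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(first)))
  v <- utils::read.csv(path, header = has_header)[[1]]
  ecg_signal(as.numeric(v), fs)
}

#' Write a signal as one-column CSV
#'
#' @param sig An [ecg_signal()].
#' @param path Output path.
#' @export
write_signal_csv <- function(sig, path) {
  utils::write.csv(data.frame(voltage = sig$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write QRS delineation to JSON
#'
#' @param delin A [delineate_beats()] result.
#' @param selection Optional [compute_scale_scores()] result.
#' @param path Output path.
#' @export
write_beats_json <- function(delin, path, selection = NULL) {
  obj <- list(n_beats = delin$n_beats, onset = delin$onset,
              peak = delin$peak, offset = delin$offset,
              polarity = delin$polarity)
  if (!is.null(selection)) {
    obj$chosen_scale <- selection$chosen_scale
    obj$scores <- as.list(selection$scores)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read QRS delineation from JSON
#'
#' @param path Path written by [write_beats_json()].
#' @return A `"qrs_delineation"` object.
#' @export
read_beats_json <- function(path) {
  if (!file.exists(path)) stop_input("beats file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(onset = as.integer(obj$onset),
                 peak = as.integer(obj$peak),
                 offset = as.integer(obj$offset),
                 polarity = as.character(obj$polarity),
                 n_beats = as.integer(obj$n_beats)),
            class = "qrs_delineation")
}

#' Read episode annotations from JSON or CSV
#'
#' @param path JSON (list of objects with `start`, `end`) or CSV with
#'   `start`, `end` columns, in seconds.
#' @return Data.frame with `start`, `end`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input("annotation file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj)
  } else {
    df <- utils::read.csv(path)
  }
  if (!all(c("start", "end") %in% names(df)))
    stop_input("annotations need 'start' and 'end' columns")
  df[, c("start", "end")]
}

#' Serialize a KDE model to JSON
#'
#' @param model A [kde_fit()] model.
#' @param path Output path.
#' @export
write_kde_json <- function(model, path) {
  obj <- list(kernel = model$kernel$name, factor = model$factor,
              bandwidths = model$bandwidths,
              priors = as.list(model$priors),
              points_S = model$points_S, points_N = model$points_N)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a KDE model from JSON
#'
#' @param path Path written by [write_kde_json()].
#' @return A `"kde_model"` object.
#' @export
read_kde_json <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(points_S = as.matrix(obj$points_S),
         points_N = as.matrix(obj$points_N),
         bandwidths = list(S = as.numeric(obj$bandwidths$S),
                           N = as.numeric(obj$bandwidths$N)),
         factor = obj$factor, kernel = kernel_spec(obj$kernel),
         priors = c(N = obj$priors$N, S = obj$priors$S)),
    class = "kde_model")
}

#' Read or write feature windows as CSV
#'
#' @param windows Data.frame with `f1`, `f2`, `f3` and optionally `label`.
#' @param path File path.
#' @export
write_windows_csv <- function(windows, path) {
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  if (!file.exists(path)) stop_input("windows file not found: %s", path)
  utils::read.csv(path)
}
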