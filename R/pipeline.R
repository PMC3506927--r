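# End-to-end pipeline and the synthetic benchmark.
#
# Benchmark study conditions: 20 records of 180 s at 250 Hz, heart rate
# 70 bpm, one 60 s episode per record with ST deviation +/-0.2 mV
# (elevation and depression alternating), 0.3 Hz drift of 0.5 mV, QRS
# detection with Daubechies8, KDE with the Gaussian kernel at bandwidth
# factor 0.5, pooled windows split 1/10 train : 9/10 test.

#' Process one annotated record into a labeled window dataset
#'
#' Baseline removal, QRS detection, feature extraction and dataset
#' assembly in one call.
#'
#' @param record A [generate_record()] result, or a list with `signal`
#'   ([ecg_signal()]) and `episodes` (data.frame `start`, `end`).
#' @param fb Filter bank or family name.
#' @param trim Episode guard band, seconds.
#' @param balance Balance normal against ischemic windows.
#' @return Labeled window data.frame (see [build_dataset()]).
#' @export
pipeline_dataset <- function(record, fb = "daubechies8", trim = 10,
                             balance = TRUE) {
  fecg <- remove_baseline(record$signal, fb)
  feats <- extract_features(fecg, fb)
  build_dataset(feats, record$episodes, record$signal$fs,
                trim = trim, balance = balance)
}

#' Generate the synthetic benchmark record set
#'
#' @param n_records Number of records (default 20).
#' @param seed Base seed; record `i` uses `seed * 1000 + i`.
#' @param st_deviation Magnitude of the ST shift (sign alternates across
#'   records so both elevation and depression are represented).
#' @param duration Record length, seconds (default 180).
#' @param episode `c(start, end)` of the single episode (default 60-120 s).
#' @param heart_rate Beats per minute (default 70).
#' @param drift_amp,drift_freq Baseline drift parameters (defaults 0.5 mV
#'   at 0.3 Hz).
#' @return List of [generate_record()] results.
#' @export
benchmark_records <- function(n_records = 20, seed = 1,
                              st_deviation = 0.2, duration = 180,
                              episode = c(60, 120), heart_rate = 70,
                              drift_amp = 0.5, drift_freq = 0.3) {
  lapply(seq_len(n_records), function(i) {
    sign_i <- if (i %% 2 == 0) -1 else 1
    generate_record(synth_config(
      duration = duration, heart_rate = heart_rate,
      st_deviation = sign_i * st_deviation,
      episodes = data.frame(start = episode[1], end = episode[2]),
      drift_amp = drift_amp, drift_freq = drift_freq,
      seed = seed * 1000 + i))
  })
}

#' Run the full synthetic benchmark
#'
#' Pools labeled windows from all records (episode ids kept distinct
#' across records), splits them, fits the requested classifier on the
#' training part and evaluates window-level sensitivity/specificity plus
#' episode-level strict-majority detection on the test part.
#'
#' @param records List of records from [benchmark_records()].
#' @param classifier `"kde"` (default) or `"svm"`.
#' @param kernel KDE kernel name.
#' @param factor KDE bandwidth factor.
#' @param C SVM trade-off parameter.
#' @param fraction Training fraction (default 1/10).
#' @param seed Seed for the split.
#' @param fb Filter bank or family name.
#' @return List with `metrics` (an `"st_metrics"`), `detected`,
#'   `n_episodes`, `detect_rate`, `n_train`, `n_test` and the fitted
#'   `model`.
#' @export
run_benchmark <- function(records, classifier = c("kde", "svm"),
                          kernel = "gaussian", factor = 0.5, C = 10,
                          fraction = 1 / 10, seed = 1,
                          fb = "daubechies8") {
  classifier <- match.arg(classifier)
  sets <- vector("list", length(records))
  for (i in seq_along(records)) {
    ds <- pipeline_dataset(records[[i]], fb)
    if (nrow(ds) > 0L) ds$episode <- ds$episode + 1000L * i
    sets[[i]] <- ds
  }
  windows <- do.call(rbind, sets)
  sp <- split_windows(windows, fraction, seed)
  if (classifier == "kde") {
    model <- kde_fit(.feature_matrix(sp$train[sp$train$label == "S", ]),
                     .feature_matrix(sp$train[sp$train$label == "N", ]),
                     kernel, factor)
    pred <- kde_classify(model, .feature_matrix(sp$test))
  } else {
    model <- train_svm(sp$train, C = C)
    pred <- predict(model, sp$test)
  }
  cm <- confusion(pred, sp$test$label)
  ep_ids <- unique(sp$test$episode[!is.na(sp$test$episode)])
  by_ep <- lapply(ep_ids, function(e) {
    pred[!is.na(sp$test$episode) & sp$test$episode == e]
  })
  detected <- count_detected(by_ep)
  list(metrics = cm, detected = detected, n_episodes = length(ep_ids),
       detect_rate = if (length(ep_ids)) detected / length(ep_ids) else NA,
       n_train = nrow(sp$train), n_test = nrow(sp$test), model = model)
}

#' Noise robustness sweep
#'
#' Adds the deterministic baseline-plus-powerline noise at each
#' amplification `a` to freshly generated records and reruns the whole
#' pipeline (training included), recording sensitivity + specificity.
#'
#' @param a_grid Amplification factors (default 0.1..1.0 step 0.1).
#' @param b Angular frequency of the added baseline, rad/s (default 6).
#' @param seeds Integer vector of base seeds (one pipeline run each).
#' @param n_records Records per run (default 6 for speed).
#' @param ... Passed to [benchmark_records()].
#' @return Data.frame with `a`, `seed`, `se`, `sp`, `sum`.
#' @export
noise_robustness <- function(a_grid = seq(0.1, 1, by = 0.1), b = 6,
                             seeds = 1:5, n_records = 6, ...) {
  out <- list()
  for (sd_i in seeds) {
    clean <- benchmark_records(n_records = n_records, seed = sd_i, ...)
    for (a in a_grid) {
      noisy <- lapply(clean, function(r) {
        r$signal <- add_noise(r$signal, a, b)
        r
      })
      res <- run_benchmark(noisy, seed = sd_i)
      out[[length(out) + 1L]] <-
        data.frame(a = a, seed = sd_i, se = res$metrics$Se,
                   sp = res$metrics$Sp,
                   sum = res$metrics$Se + res$metrics$Sp)
    }
  }
  do.call(rbind, out)
}
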