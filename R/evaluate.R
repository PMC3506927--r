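# Dataset assembly, splitting and window/episode metrics.

#' Assemble a labeled window dataset from a processed record
#'
#' Windows are labeled by the episode membership of their time midpoint.
#' A 10 s guard band on each side of every episode boundary is excluded:
#' windows overlapping a guard band are dropped. Normal windows are then
#' taken from the start of the record, as many as there are ischemic
#' windows, to keep the classes balanced.
#'
#' @param feats An [extract_features()] result for the flattened record.
#' @param episodes Data.frame with `start`, `end` columns in seconds.
#' @param fs Sampling frequency of the record, Hz.
#' @param trim Guard band half-width in seconds (default 10).
#' @param balance Balance normal windows against ischemic ones
#'   (default TRUE).
#' @return Data.frame with `f1`, `f2`, `f3`, `label` (`"N"`/`"S"`),
#'   `episode` (episode row index or `NA`) and `t_mid` (seconds).
#' @export
build_dataset <- function(feats, episodes, fs, trim = 10, balance = TRUE) {
  win <- feats$windows
  beats <- feats$beats
  if (nrow(win) == 0L)
    return(data.frame(f1 = numeric(0), f2 = numeric(0), f3 = numeric(0),
                      label = character(0), episode = integer(0),
                      t_mid = numeric(0)))
  t_start <- (beats$peak[win$first_beat] - 1) / fs
  t_end <- (beats$peak[win$last_beat] - 1) / fs
  t_mid <- (t_start + t_end) / 2
  ne <- nrow(episodes)
  if (ne == 0L)
    warning("build_dataset: record has no annotated episodes")
  in_margin <- rep(FALSE, nrow(win))
  ep_id <- rep(NA_integer_, nrow(win))
  if (ne > 0L) {
    for (e in seq_len(ne)) {
      s <- episodes$start[e]; en <- episodes$end[e]
      for (mz in list(c(s - trim, s + trim), c(en - trim, en + trim)))
        in_margin <- in_margin | (t_end > mz[1] & t_start < mz[2])
      hit <- t_mid > s & t_mid < en
      ep_id[hit] <- e
    }
  }
  keep <- !in_margin
  out <- data.frame(f1 = win$f1, f2 = win$f2, f3 = win$f3,
                    label = ifelse(is.na(ep_id), "N", "S"),
                    episode = ep_id, t_mid = t_mid)[keep, , drop = FALSE]
  if (balance) {
    n_s <- sum(out$label == "S")
    idx_n <- which(out$label == "N")
    ord <- idx_n[order(out$t_mid[idx_n])]
    if (length(ord) > n_s)
      out <- out[-ord[(n_s + 1):length(ord)], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Assigns `floor(n * fraction)` windows of each class to the training
#' set, sampling at random under the given seed, and the rest to the test
#' set.
#'
#' @param windows Labeled window data.frame (column `label`).
#' @param fraction Training fraction in (0, 1); default 1/10. Records with
#'   very little ischemic data are conventionally split at 1/3 instead.
#' @param seed Integer seed making the split deterministic.
#' @return List with `train` and `test` data.frames.
#' @export
split_windows <- function(windows, fraction = 1 / 10, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop_config("split_windows: fraction must be in (0, 1)")
  labs <- unique(windows$label)
  counts <- table(windows$label)
  if (any(counts < 2L))
    stop_fit("split_windows: class '%s' has fewer than 2 windows",
             names(counts)[which(counts < 2L)[1]])
  .with_seed(seed, {
    train_idx <- integer(0)
    for (cl in labs) {
      idx <- which(windows$label == cl)
      n_tr <- max(1L, floor(length(idx) * fraction))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
    list(train = windows[train_idx, , drop = FALSE],
         test = windows[-train_idx, , drop = FALSE])
  })
}

#' Window-level confusion metrics
#'
#' Ischemic (`"S"`) is the positive class: `Se = TP / (TP + FN)` and
#' `Sp = TN / (TN + FP)`.
#'
#' @param pred,truth Character vectors of `"N"`/`"S"` labels.
#' @return An object of class `"st_metrics"`: list with `TP`, `FN`, `FP`,
#'   `TN`, `Se`, `Sp`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop_input("confusion: prediction and truth lengths differ")
  tp <- sum(pred == "S" & truth == "S")
  fn <- sum(pred == "N" & truth == "S")
  fp <- sum(pred == "S" & truth == "N")
  tn <- sum(pred == "N" & truth == "N")
  structure(list(TP = tp, FN = fn, FP = fp, TN = tn,
                 Se = tp / (tp + fn), Sp = tn / (tn + fp)),
            class = "st_metrics")
}

#' @export
print.st_metrics <- function(x, ...) {
  cat(sprintf("Se %.3f  Sp %.3f  (TP %d FN %d FP %d TN %d)\n",
              x$Se, x$Sp, x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Count detected episodes by strict majority
#'
#' Applies the strict-majority rule of [classify_episode()] to each
#' episode's window labels.
#'
#' @param labels_by_episode List of character label vectors, one per
#'   episode.
#' @return Integer count of detected episodes.
#' @export
count_detected <- function(labels_by_episode) {
  sum(vapply(labels_by_episode, classify_episode, logical(1)))
}
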