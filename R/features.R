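# ST-morphology features.
#
# All measurements are taken on the flattened signal relative to the
# record's "effective zero voltage": the mean fecg value over QRS onset
# points. Per-beat landmarks use the record-mean onset/offset gaps
# (truncated to integers) applied around each detected peak, as the
# executable pseudocode form prescribes, rather than the per-beat
# delineated onsets/offsets. The accumulation loops below are deliberately
# plain left-to-right sums so results are reproducible to the bit against
# a literal transcription of the procedure.

#' Record-level feature context
#'
#' Computes the truncated mean peak-onset and offset-peak index gaps and
#' the effective zero voltage (mean `fecg` at QRS onsets).
#'
#' @param fecg Flattened [ecg_signal()].
#' @param delin A [delineate_beats()] result.
#' @return List with `ref_voltage`, `mean_idx_diff_1`, `mean_idx_diff_2`.
#' @export
compute_context <- function(fecg, delin) {
  n <- delin$n_beats
  if (n < 1L) stop_input("compute_context: no beats")
  x <- fecg$samples
  s1 <- 0; s2 <- 0; s3 <- 0
  for (i in seq_len(n)) {
    s1 <- s1 + (delin$peak[i] - delin$onset[i])
    s2 <- s2 + (delin$offset[i] - delin$peak[i])
    s3 <- s3 + x[delin$onset[i]]
  }
  list(ref_voltage = s3 / n,
       mean_idx_diff_1 = trunc(s1 / n),
       mean_idx_diff_2 = trunc(s2 / n))
}

# T-search window end for the beat whose offset proxy is k:
# k + round(0.4 * fs), clipped to the next beat's onset proxy when that is
# closer, and to the record end.
.t_window_end <- function(k, fs, n, next_m = NA_integer_,
                          t_window = 0.4) {
  w_end <- k + as.integer(round(t_window * fs))
  if (!is.na(next_m) && next_m < w_end) w_end <- next_m
  min(w_end, n)
}

#' Locate the T-wave apex after a QRS offset proxy
#'
#' The T peak is the sample with maximum `|fecg - ref|` in the window
#' `(k, k + round(0.4 fs)]`, clipped at the next beat's onset proxy; an
#' empty window falls back to `k + 1`. Ties break to the earliest sample.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param k Offset proxy (1-based sample index).
#' @param ref_voltage Effective zero voltage.
#' @param next_m Onset proxy of the next beat, or `NA` for the last beat.
#' @param t_window Search window length in seconds (default 0.4).
#' @return 1-based sample index of the T apex.
#' @export
find_t_peak <- function(fecg, k, ref_voltage, next_m = NA_integer_,
                        t_window = 0.4) {
  n <- length(fecg$samples)
  w_end <- .t_window_end(k, fecg$fs, n, next_m, t_window)
  if (w_end <= k) return(min(k + 1L, n))
  best <- k + 1L
  best_dev <- -1
  for (i in (k + 1L):w_end) {
    dev <- abs(fecg$samples[i] - ref_voltage)
    if (dev > best_dev) { best_dev <- dev; best <- i }
  }
  best
}

#' Locate the return-to-reference point F
#'
#' The first sample after the offset proxy at which the flattened voltage
#' touches or crosses the effective zero level (the deviation changes sign
#' relative to the deviation at the proxy, or is exactly zero). If the
#' voltage never returns within the T-search window, the window end is
#' used.
#'
#' @inheritParams find_t_peak
#' @return 1-based sample index of F.
#' @export
find_f_point <- function(fecg, k, ref_voltage, next_m = NA_integer_,
                         t_window = 0.4) {
  x <- fecg$samples
  n <- length(x)
  w_end <- .t_window_end(k, fecg$fs, n, next_m, t_window)
  if (w_end <= k) return(min(k + 1L, n))
  d0 <- x[k] - ref_voltage
  for (i in (k + 1L):w_end) {
    if ((x[i] - ref_voltage) * d0 <= 0) return(i)
  }
  w_end
}

#' Per-beat ST-morphology features
#'
#' For each beat with peak `p`, offset proxy `k = p + mean_idx_diff_2` and
#' onset proxy `m = p - mean_idx_diff_1`:
#' * `f1`: signed sum of `fecg - ref` from `k` to the T apex (ST/T area
#'   relative to the effective zero);
#' * `f2`: signed sum of `fecg - ref` from `k` to the F point, divided by
#'   `fecg[p]` (area normalized by R amplitude);
#' * `f3`: chord slope `(fecg[k] - fecg[m]) / (k - m)` across the QRS.
#'
#' Beats whose proxies or search window leave the record, or whose peak
#' voltage is exactly zero (undefined `f2`), are dropped with a warning.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param delin A [delineate_beats()] result.
#' @param ctx Optional [compute_context()] result (computed if missing).
#' @param t_window T-search window in seconds (default 0.4).
#' @return List with `beats` (data.frame: `peak`, `onset_proxy`,
#'   `offset_proxy`, `t_peak`, `f_point`, `f1`, `f2`, `f3`) and `context`.
#' @export
beat_features <- function(fecg, delin, ctx = NULL, t_window = 0.4) {
  if (is.null(ctx)) ctx <- compute_context(fecg, delin)
  x <- fecg$samples
  n <- length(x)
  ref <- ctx$ref_voltage
  md1 <- ctx$mean_idx_diff_1
  md2 <- ctx$mean_idx_diff_2
  nb <- delin$n_beats
  rows <- vector("list", nb)
  dropped <- 0L
  for (i in seq_len(nb)) {
    p <- delin$peak[i]
    k <- p + md2
    m <- p - md1
    next_m <- if (i < nb) delin$peak[i + 1L] - md1 else NA_integer_
    if (m < 1L || k + 1L > n) { dropped <- dropped + 1L; next }
    if (x[p] == 0) { dropped <- dropped + 1L; next }
    tp <- find_t_peak(fecg, k, ref, next_m, t_window)
    fp <- find_f_point(fecg, k, ref, next_m, t_window)
    f1 <- 0
    for (j in k:tp) f1 <- f1 + (x[j] - ref)
    s2 <- 0
    for (j in k:fp) s2 <- s2 + (x[j] - ref)
    f2 <- s2 / x[p]
    f3 <- (x[k] - x[m]) / (k - m)
    rows[[i]] <- data.frame(peak = p, onset_proxy = m, offset_proxy = k,
                            t_peak = tp, f_point = fp,
                            f1 = f1, f2 = f2, f3 = f3)
  }
  if (dropped > 0L)
    warning(sprintf("beat_features: dropped %d beat(s) at record edges or with zero peak voltage",
                    dropped))
  beats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(beats))
    beats <- data.frame(peak = integer(0), onset_proxy = integer(0),
                        offset_proxy = integer(0), t_peak = integer(0),
                        f_point = integer(0), f1 = numeric(0),
                        f2 = numeric(0), f3 = numeric(0))
  list(beats = beats, context = ctx)
}

#' Average beat features over five-beat windows
#'
#' Groups consecutive beats into non-overlapping windows of five and
#' averages each feature; a trailing remainder of fewer than five beats is
#' discarded.
#'
#' @param beats Beat-level data.frame from [beat_features()].
#' @param label Optional class label (`"N"`, `"S"`, or `NA`) attached to
#'   every window.
#' @return Data.frame with `window_id`, `f1`, `f2`, `f3`, `label`,
#'   `first_beat`, `last_beat` (row indices into `beats`); zero rows when
#'   fewer than five beats are available.
#' @export
window_features <- function(beats, label = NA_character_) {
  nb <- nrow(beats)
  nw <- nb %/% 5L
  if (nw == 0L)
    return(data.frame(window_id = integer(0), f1 = numeric(0),
                      f2 = numeric(0), f3 = numeric(0),
                      label = character(0), first_beat = integer(0),
                      last_beat = integer(0)))
  out <- vector("list", nw)
  for (w in seq_len(nw)) {
    lo <- 5L * w - 4L
    a1 <- 0; a2 <- 0; a3 <- 0
    for (j in lo:(5L * w)) {
      a1 <- a1 + beats$f1[j]
      a2 <- a2 + beats$f2[j]
      a3 <- a3 + beats$f3[j]
    }
    out[[w]] <- data.frame(window_id = w, f1 = a1 / 5, f2 = a2 / 5,
                           f3 = a3 / 5, label = label,
                           first_beat = lo, last_beat = 5L * w)
  }
  do.call(rbind, out)
}

#' Flattened record to feature windows
#'
#' Convenience wrapper: QRS detection, beat features and five-beat window
#' averaging in one call.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param fb Filter bank or family name.
#' @param label Optional label for all windows.
#' @param ... Passed to [detect_peaks()] via [detect_qrs()].
#' @return List with `windows` (data.frame), `beats`, `context`,
#'   `delineation` and `selection`.
#' @export
extract_features <- function(fecg, fb = "daubechies8",
                             label = NA_character_, ...) {
  q <- detect_qrs(fecg, fb, ...)
  bf <- beat_features(fecg, q$delineation)
  list(windows = window_features(bf$beats, label), beats = bf$beats,
       context = bf$context, delineation = q$delineation,
       selection = q$selection)
}
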