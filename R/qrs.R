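# QRS detection on the flattened signal fecg(n).
#
# The QRS-dominant wavelet scale is chosen by scoring each single-band
# reconstruction pulse_j(n) against fecg(n) and taking the scale with the
# largest drop score_j - score_{j+1} over j in [2, k-2]. Peaks are local
# maxima of the needle signal fecg(n) * pulse(n); onset/offset follow the
# two-direction-change walk away from each peak.

#' Single detail-band reconstruction
#'
#' Inverse transform keeping only detail band `j` (the approximation and the
#' deepest detail band are never kept during scale selection).
#'
#' @param fecg Flattened [ecg_signal()].
#' @param fb Filter bank or family name.
#' @param j Detail scale to keep, `1 <= j <= depth - 1`.
#' @param depth Decomposition depth; defaults to
#'   [decomposition_depth()] of the sampling frequency.
#' @return An [ecg_signal()] holding `pulse(n)`.
#' @export
band_reconstruction <- function(fecg, fb = "daubechies8", j, depth = NULL) {
  fb <- .as_filter_bank(fb)
  if (is.null(depth)) depth <- decomposition_depth(fecg$fs)
  cf <- wavedec(fecg$samples, fb, depth)
  if (j < 1 || j > cf$depth - 1L)
    stop_input("band_reconstruction: scale %d outside 1..%d", j, cf$depth - 1L)
  ecg_signal(waverec_bands(cf, fb, keep_details = j), fecg$fs)
}

#' Score wavelet scales and select the QRS-dominant one
#'
#' For each detail scale `j` the score is
#' `sum(fecg * pulse_j) / sum(|pulse_j|)` — how strongly the band
#' reconstruction protrudes where the signal does, per unit band amplitude.
#' The chosen scale maximizes `score_j - score_{j+1}` over `j` in
#' `[2, depth - 2]`; ties break toward the smallest scale. An all-zero band
#' scores 0.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param fb Filter bank or family name.
#' @param denominator `"abs"` (default) uses `sum(|pulse|)`;
#'   `"literal"` uses the plain `sum(pulse)`, which is near zero for any
#'   zero-mean detail band and is provided only for parity experiments.
#' @return An object of class `"scale_selection"`: list with `scores`
#'   (named by scale), `chosen_scale`, `pulse` (the [ecg_signal()]
#'   reconstruction at the chosen scale) and `depth`.
#' @export
compute_scale_scores <- function(fecg, fb = "daubechies8",
                                 denominator = c("abs", "literal")) {
  fb <- .as_filter_bank(fb)
  denominator <- match.arg(denominator)
  depth <- decomposition_depth(fecg$fs)
  cf <- wavedec(fecg$samples, fb, depth)
  k <- cf$depth
  if (k < 4L)
    stop_input("scale scoring needs depth >= 4 (record too short; depth %d)", k)
  x <- fecg$samples
  scores <- numeric(k - 1L)
  pulses <- vector("list", k - 1L)
  for (j in seq_len(k - 1L)) {
    p <- waverec_bands(cf, fb, keep_details = j)
    pulses[[j]] <- p
    den <- if (denominator == "abs") sum(abs(p)) else sum(p)
    scores[j] <- if (den == 0) 0 else sum(x * p) / den
  }
  names(scores) <- seq_len(k - 1L)
  cand <- 2:(k - 2L)
  drops <- scores[cand] - scores[cand + 1L]
  chosen <- cand[which.max(drops)]   # which.max: first max, smallest j wins
  structure(
    list(scores = scores, chosen_scale = chosen,
         pulse = ecg_signal(pulses[[chosen]], fecg$fs), depth = k),
    class = "scale_selection")
}

#' @export
print.scale_selection <- function(x, ...) {
  cat(sprintf("<scale_selection> chosen scale %d of depth %d\n",
              x$chosen_scale, x$depth))
  print(signif(x$scores, 4))
  invisible(x)
}

#' Locate QRS peaks on the needle signal
#'
#' The needle signal is the pointwise product `fecg * pulse`; it spikes at
#' QRS complexes regardless of whether they protrude upward or downward.
#' Local maxima above a relative threshold are kept, separated by a
#' refractory period, and each is snapped to the extremum of `|fecg|`
#' within a small window so the reported index sits on the R (or deepest
#' negative) peak itself.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param pulse Band reconstruction at the chosen scale ([ecg_signal()]).
#' @param threshold_frac Detection threshold as a fraction of the needle's
#'   98th percentile (default 0.1; thresholding is relative, so rescaling
#'   the signal does not move the peaks).
#' @param refractory Minimum peak separation in seconds (default 0.35:
#'   longer than the R-to-T-apex interval, so the stronger QRS spike
#'   suppresses T-wave needle maxima, yet shorter than the RR interval at
#'   any plausible exercise heart rate).
#' @param snap_window Half-width, in seconds, of the `|fecg|` snapping
#'   window (default 0.04).
#' @return Sorted integer vector of 1-based peak indices (empty for a flat
#'   record).
#' @export
detect_peaks <- function(fecg, pulse, threshold_frac = 0.1,
                         refractory = 0.35, snap_window = 0.04) {
  x <- fecg$samples
  p <- if (inherits(pulse, "ecg_signal")) pulse$samples else pulse
  if (length(x) != length(p))
    stop_input("detect_peaks: fecg and pulse lengths differ")
  needle <- x * p
  n <- length(needle)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  is_max <- needle[i] > needle[i - 1L] & needle[i] >= needle[i + 1L]
  cand <- i[is_max]
  thr <- threshold_frac * as.numeric(stats::quantile(needle, 0.98))
  cand <- cand[needle[cand] > thr]
  if (length(cand) == 0L) return(integer(0))
  gap <- max(1L, as.integer(round(refractory * fecg$fs)))
  # strongest-first greedy suppression within the refractory gap
  cand <- cand[order(needle[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (cidx in cand) {
    if (all(abs(kept - cidx) >= gap)) kept <- c(kept, cidx)
  }
  # snap to the |fecg| extremum nearby, then re-enforce the gap
  w <- as.integer(round(snap_window * fecg$fs))
  snapped <- vapply(kept, function(cidx) {
    lo <- max(1L, cidx - w); hi <- min(n, cidx + w)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  snapped <- sort(unique(snapped))
  if (length(snapped) > 1L) {
    keep <- rep(TRUE, length(snapped))
    last <- 1L
    for (idx in 2:length(snapped)) {
      if (snapped[idx] - snapped[last] < gap) {
        if (abs(x[snapped[idx]]) > abs(x[snapped[last]])) {
          keep[last] <- FALSE; last <- idx
        } else keep[idx] <- FALSE
      } else last <- idx
    }
    snapped <- snapped[keep]
  }
  snapped
}

.walk_back <- function(w, p) {
  j <- 1L
  repeat {                      # phase 1: ride the rising slope (non-strict)
    if (p - j < 1L) return(NA_integer_)
    if (w[p - j] <= w[p - j + 1L]) j <- j + 1L else break
  }
  repeat {                      # phase 2: ride the falling slope (strict)
    if (p - j < 1L) return(NA_integer_)
    if (w[p - j] > w[p - j + 1L]) j <- j + 1L else break
  }
  p - j
}

.walk_fwd <- function(w, p) {
  n <- length(w)
  j <- 1L
  repeat {
    if (p + j > n) return(NA_integer_)
    if (w[p + j - 1L] >= w[p + j]) j <- j + 1L else break
  }
  repeat {
    if (p + j > n) return(NA_integer_)
    if (w[p + j - 1L] < w[p + j]) j <- j + 1L else break
  }
  p + j
}

#' Delineate QRS onset and offset around each peak
#'
#' Walks backward (forward) from each peak until the direction of
#' rise/fall of `fecg` changes twice; the sample reached is the onset
#' (offset). Downward-protruding complexes (`fecg[peak] <= 0`) use the same
#' walk with all inequalities mirrored, which equals running the upward
#' walk on `-fecg`. Beats whose walk would leave the record are dropped.
#'
#' @param fecg Flattened [ecg_signal()].
#' @param peaks Integer vector of 1-based peak indices.
#' @return An object of class `"qrs_delineation"`: list with equal-length
#'   integer vectors `onset`, `peak`, `offset`, character `polarity`
#'   (`"up"`/`"down"`), and `n_beats`.
#' @examples
#' d <- delineate_beats(ecg_signal(c(0, 1, 0, 5, 0, 1, 0), 250), peaks = 4L)
#' c(d$onset, d$offset)  # 1 and 7
#' @export
delineate_beats <- function(fecg, peaks) {
  x <- fecg$samples
  peaks <- as.integer(peaks)
  if (any(peaks < 1L | peaks > length(x)))
    stop_input("delineate_beats: peak index outside the record")
  onset <- offset <- integer(0)
  pol <- character(0)
  kept <- integer(0)
  for (p in peaks) {
    up <- x[p] > 0
    w <- if (up) x else -x
    on <- .walk_back(w, p)
    off <- .walk_fwd(w, p)
    if (is.na(on) || is.na(off)) next   # walk left the record: drop beat
    kept <- c(kept, p)
    onset <- c(onset, on)
    offset <- c(offset, off)
    pol <- c(pol, if (up) "up" else "down")
  }
  structure(list(onset = onset, peak = kept, offset = offset,
                 polarity = pol, n_beats = length(kept)),
            class = "qrs_delineation")
}

#' @export
print.qrs_delineation <- function(x, ...) {
  cat(sprintf("<qrs_delineation> %d beats\n", x$n_beats))
  invisible(x)
}

#' Full QRS detection on a flattened record
#'
#' Convenience wrapper chaining [compute_scale_scores()], [detect_peaks()]
#' and [delineate_beats()].
#'
#' @param fecg Flattened [ecg_signal()].
#' @param fb Filter bank or family name.
#' @param ... Passed to [detect_peaks()].
#' @return List with `selection` (the [compute_scale_scores()] result),
#'   `peaks` and `delineation`.
#' @export
detect_qrs <- function(fecg, fb = "daubechies8", ...) {
  sel <- compute_scale_scores(fecg, fb)
  peaks <- detect_peaks(fecg, sel$pulse, ...)
  list(selection = sel, peaks = peaks,
       delineation = delineate_beats(fecg, peaks))
}
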