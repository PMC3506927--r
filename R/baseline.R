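# Baseline wander removal.
#
# Decompose to depth k = ceiling(log2(fs)) so the approximation band falls
# below 0.5 Hz, zero every detail band, and reconstruct: the result is the
# wandering baseline. Subtracting it flattens the record without touching
# QRS/T morphology the way a sharp cutoff filter would.

#' Estimate sub-0.5 Hz baseline wander
#'
#' Wavelet-decomposes the record to depth `k = ceiling(log2(fs))` (capped,
#' with a warning, at the deepest feasible level for short records), zeroes
#' all detail bands and reconstructs from the approximation alone.
#'
#' @param ecg An [ecg_signal()].
#' @param fb Filter bank or family name (default `"daubechies8"`).
#' @param depth Optional depth override; defaults to
#'   [decomposition_depth()] of the sampling frequency.
#' @return An [ecg_signal()] holding `baseline(n)`, same length and fs.
#' @export
estimate_baseline <- function(ecg, fb = "daubechies8", depth = NULL) {
  fb <- .as_filter_bank(fb)
  if (length(ecg$samples) < fb$length)
    stop_input("record (%d samples) shorter than the wavelet filter (%d)",
               length(ecg$samples), fb$length)
  if (is.null(depth)) depth <- decomposition_depth(ecg$fs)
  cf <- wavedec(ecg$samples, fb, depth)
  ecg_signal(waverec_bands(cf, fb, keep_approx = TRUE), ecg$fs)
}

#' Remove baseline wander
#'
#' Returns the flattened signal `fecg(n) = ecg(n) - baseline(n)`.
#'
#' @inheritParams estimate_baseline
#' @return An [ecg_signal()] holding the flattened record.
#' @examples
#' rec <- generate_record(synth_config(duration = 30, drift_amp = 0.5,
#'                                     seed = 1))
#' fecg <- remove_baseline(rec$signal)
#' @export
remove_baseline <- function(ecg, fb = "daubechies8", depth = NULL) {
  bl <- estimate_baseline(ecg, fb, depth)
  ecg_signal(ecg$samples - bl$samples, ecg$fs)
}
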