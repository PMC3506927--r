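#' ECG signal container
#'
#' A light container pairing voltage samples with their sampling frequency.
#' Sample indices throughout the package are 1-based, following the R
#' convention; times are `(index - 1) / fs` seconds.
#'
#' @param samples Numeric vector of voltages (arbitrary consistent units,
#'   conventionally mV). Must be finite.
#' @param fs Sampling frequency in Hz (> 0).
#' @return An object of class `"ecg_signal"`.
#' @export
ecg_signal <- function(samples, fs) {
  if (!is.numeric(samples)) stop_input("ecg_signal: samples must be numeric")
  if (!all(is.finite(samples)))
    stop_input("ecg_signal: samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_input("ecg_signal: fs must be a positive number")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "ecg_signal")
}

.as_signal <- function(x, fs = NULL) {
  if (inherits(x, "ecg_signal")) return(x)
  if (is.null(fs))
    stop_input("a plain numeric signal needs an explicit fs")
  ecg_signal(x, fs)
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)
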