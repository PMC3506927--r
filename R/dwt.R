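# Periodized orthogonal DWT.
#
# Boundary convention: circular (periodized) filtering; an odd-length input
# is first extended by repeating its last sample, so every analysis step
# halves the length exactly (ceil(n/2)) and reconstruction is exact after
# truncating back to the recorded per-level lengths.
# Downsampling phase: the even-indexed outputs of the correlation
# y[k] = sum_n h[n] x[(k + n) mod N] are kept, i.e.
# a[i] = sum_n h[n] x[(2i + n) mod N] (0-based i, n).

#' Single-level discrete wavelet transform
#'
#' One analysis step of the periodized orthogonal DWT: circular lowpass and
#' highpass filtering followed by dyadic downsampling. Odd-length input is
#' extended by repeating the last sample, so both outputs have length
#' `ceiling(length(x) / 2)`.
#'
#' @param x Numeric vector (non-empty).
#' @param fb A [wavelet_filters()] filter bank, or a family name.
#' @return List with numeric vectors `approx` and `detail`.
#' @examples
#' dwt_step(c(1, 1, 1, 1), "haar")  # approx sqrt(2), detail 0
#' @export
dwt_step <- function(x, fb) {
  fb <- .as_filter_bank(fb)
  if (length(x) == 0L) stop_input("dwt_step: empty input signal")
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  n <- length(x)
  m <- n %/% 2L
  h <- fb$lowpass; g <- fb$highpass
  a <- numeric(m); d <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (tap in seq_len(fb$length)) {
    idx <- (base + (tap - 1L)) %% n + 1L
    xi <- x[idx]
    a <- a + h[tap] * xi
    d <- d + g[tap] * xi
  }
  list(approx = a, detail = d)
}

#' Single-level inverse discrete wavelet transform
#'
#' Exact inverse of [dwt_step()] under the same periodized convention.
#'
#' @param approx,detail Numeric vectors of equal length.
#' @param fb Filter bank or family name.
#' @return Numeric vector of length `2 * length(approx)`.
#' @export
idwt_step <- function(approx, detail, fb) {
  fb <- .as_filter_bank(fb)
  m <- length(approx)
  if (m != length(detail))
    stop_input("idwt_step: approx and detail lengths differ (%d vs %d)",
               m, length(detail))
  if (m == 0L) stop_input("idwt_step: empty input")
  n <- 2L * m
  h <- fb$lowpass; g <- fb$highpass
  out <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (tap in seq_len(fb$length)) {
    idx <- (base + (tap - 1L)) %% n + 1L
    out[idx] <- out[idx] + h[tap] * approx + g[tap] * detail
  }
  out
}

#' Multi-level wavelet decomposition
#'
#' Iterates [dwt_step()] on the running approximation. If a further step
#' would act on a sequence shorter than the filter, decomposition stops
#' early and the achieved depth is recorded (with a warning).
#'
#' @param x Numeric vector.
#' @param fb Filter bank or family name.
#' @param depth Requested number of levels (>= 1).
#' @return An object of class `"wavelet_coeffs"`: list with `wavelet`,
#'   `depth` (achieved), `approx`, `details` (list indexed by scale
#'   `1..depth`), `original_length` and `level_lengths` (input length at
#'   each level, used to undo the odd-length extension on reconstruction).
#' @export
wavedec <- function(x, fb, depth) {
  fb <- .as_filter_bank(fb)
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop_config("wavedec: depth must be a positive integer")
  depth <- as.integer(depth)
  if (length(x) == 0L) stop_input("wavedec: empty input signal")
  cur <- as.numeric(x)
  details <- vector("list", depth)
  level_lengths <- integer(0)
  achieved <- 0L
  for (j in seq_len(depth)) {
    if (length(cur) < fb$length) {
      warning(sprintf(
        "wavedec: stopping at depth %d (working length %d < filter length %d)",
        achieved, length(cur), fb$length))
      break
    }
    level_lengths[j] <- length(cur)
    st <- dwt_step(cur, fb)
    details[[j]] <- st$detail
    cur <- st$approx
    achieved <- j
  }
  if (achieved == 0L)
    stop_input("wavedec: record shorter than the wavelet filter (%d < %d)",
               length(x), fb$length)
  structure(
    list(wavelet = fb$name, depth = achieved,
         approx = cur, details = details[seq_len(achieved)],
         original_length = length(x), level_lengths = level_lengths),
    class = "wavelet_coeffs")
}

#' Multi-level wavelet reconstruction
#'
#' Inverts [wavedec()]: `waverec(wavedec(x, fb, k), fb)` recovers `x` up to
#' floating-point round-off for every supported family.
#'
#' @param coeffs A `"wavelet_coeffs"` object.
#' @param fb Filter bank or family name (must match `coeffs$wavelet`).
#' @return Numeric vector of length `coeffs$original_length`.
#' @export
waverec <- function(coeffs, fb) {
  fb <- .as_filter_bank(fb)
  k <- coeffs$depth
  cur <- coeffs$approx
  if (length(cur) != length(coeffs$details[[k]]))
    stop_input("waverec: approx/detail length mismatch at depth %d", k)
  for (j in rev(seq_len(k))) {
    d <- coeffs$details[[j]]
    if (length(d) != length(cur))
      stop_input("waverec: inconsistent coefficient lengths at scale %d", j)
    cur <- idwt_step(cur, d, fb)
    cur <- cur[seq_len(coeffs$level_lengths[j])]
  }
  cur
}

#' Reconstruct with selected bands zeroed
#'
#' Helper used by baseline estimation (keep approximation only) and QRS
#' scale scoring (keep a single detail band).
#'
#' @param coeffs A `"wavelet_coeffs"` object.
#' @param fb Filter bank or family name.
#' @param keep_approx Keep the approximation band?
#' @param keep_details Integer vector of detail scales to keep (others zeroed).
#' @return Numeric vector, same length as the original signal.
#' @export
waverec_bands <- function(coeffs, fb, keep_approx = FALSE,
                          keep_details = integer(0)) {
  bad <- setdiff(keep_details, seq_len(coeffs$depth))
  if (length(bad) > 0L)
    stop_input("waverec_bands: detail scale(s) %s out of range 1..%d",
               paste(bad, collapse = ","), coeffs$depth)
  cf <- coeffs
  if (!keep_approx) cf$approx <- numeric(length(cf$approx))
  for (j in seq_len(cf$depth)) {
    if (!(j %in% keep_details))
      cf$details[[j]] <- numeric(length(cf$details[[j]]))
  }
  waverec(cf, fb)
}

#' Decomposition depth for baseline separation
#'
#' The smallest depth `k` with `fs / 2^(k+1) <= 1/2` Hz, i.e.
#' `k = ceiling(log2(fs))`: at that depth the approximation band lies
#' entirely below 0.5 Hz, where baseline wander resides.
#'
#' @param fs Sampling frequency in Hz (> 0).
#' @return Integer depth, e.g. `decomposition_depth(250) == 8`.
#' @export
decomposition_depth <- function(fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_input("decomposition_depth: sampling frequency must be positive")
  as.integer(ceiling(log2(fs)))
}

#' Nominal dyadic frequency band of a coefficient sequence
#'
#' @param level Detail scale `j` (1 <= j <= depth), or the depth `k` when
#'   `band = "approx"`.
#' @param fs Sampling frequency in Hz.
#' @param band `"detail"` (default) or `"approx"`.
#' @return Numeric `c(low, high)` in Hz: detail scale `j` occupies
#'   `(fs/2^(j+1), fs/2^j)`; the depth-`k` approximation occupies
#'   `(0, fs/2^(k+1))`.
#' @export
frequency_band <- function(level, fs, band = c("detail", "approx")) {
  band <- match.arg(band)
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level != floor(level))
    stop_input("frequency_band: level must be a positive integer")
  if (fs <= 0) stop_input("frequency_band: fs must be positive")
  if (band == "detail") c(low = fs / 2^(level + 1), high = fs / 2^level)
  else c(low = 0, high = fs / 2^(level + 1))
}
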