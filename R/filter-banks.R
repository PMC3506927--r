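# Orthonormal lowpass taps h_0..h_{L-1}, transcribed from the published
# Daubechies / Coiflet coefficient tables (>= 15 significant digits).
# Convention: sum(h) = sqrt(2), sum(h^2) = 1.
.wavelet_taps <- list(
  haar = c(
    7.07106781186547573e-01,
    7.07106781186547573e-01
  ),
  daubechies4 = c(
    4.82962913144534156e-01,
    8.36516303737807942e-01,
    2.24143868042013389e-01,
    -1.29409522551260370e-01
  ),
  daubechies8 = c(
    2.30377813308896506e-01,
    7.14846570552915672e-01,
    6.30880767929858921e-01,
    -2.79837694168598543e-02,
    -1.87034811719093086e-01,
    3.08413818355607640e-02,
    3.28830116668851966e-02,
    -1.05974017850690317e-02
  ),
  daubechies10 = c(
    1.60102397974192928e-01,
    6.03829269797189649e-01,
    7.24308528437772936e-01,
    1.38428145901320743e-01,
    -2.42294887066382025e-01,
    -3.22448695846383748e-02,
    7.75714938400457188e-02,
    -6.24149021279827437e-03,
    -1.25807519990819988e-02,
    3.33572528547377125e-03
  ),
  coiflet6 = c(
    -7.27326195125264502e-02,
    3.37897662457481818e-01,
    8.52572020211600390e-01,
    3.84864846864857779e-01,
    -7.27326195125264502e-02,
    -1.56557281357919929e-02
  ),
  coiflet12 = c(
    1.63873364632036410e-02,
    -4.14649367868717769e-02,
    -6.73725547237255945e-02,
    3.86110066822762887e-01,
    8.12723635449413506e-01,
    4.17005184423239084e-01,
    -7.64885990782807612e-02,
    -5.94344186464310920e-02,
    2.36801719468477702e-02,
    5.61143481936883428e-03,
    -1.82320887091103230e-03,
    -7.20549445520346976e-04
  ),
  coiflet18 = c(
    -3.79351286438080193e-03,
    7.78259642567274632e-03,
    2.34526961420771680e-02,
    -6.57719112814693641e-02,
    -6.11233900029725524e-02,
    4.05176902409118245e-01,
    7.93777222626087187e-01,
    4.28483476377369998e-01,
    -7.17998216191548383e-02,
    -8.23019271062998270e-02,
    3.45550275732977377e-02,
    1.58805448636694518e-02,
    -9.00797613673062422e-03,
    -2.57451768813679724e-03,
    1.11751877083063030e-03,
    4.66216959820402882e-04,
    -7.09833025063790038e-05,
    -3.45997731972727806e-05
  )
)

# Accepted spellings for each family, normalized to the canonical name.
.wavelet_aliases <- c(
  haar = "haar", daub4 = "daubechies4", daub8 = "daubechies8",
  daub10 = "daubechies10", daubechies4 = "daubechies4",
  daubechies8 = "daubechies8", daubechies10 = "daubechies10",
  coif6 = "coiflet6", coif12 = "coiflet12", coif18 = "coiflet18",
  coiflet6 = "coiflet6", coiflet12 = "coiflet12", coiflet18 = "coiflet18"
)

#' Supported wavelet families
#'
#' @return Character vector of the seven supported orthonormal wavelet
#'   family names. The number in each name is the filter length (Haar = 2).
#' @export
wavelet_families <- function() names(.wavelet_taps)

#' Build an orthonormal wavelet filter bank
#'
#' Returns the analysis filter pair of one of the seven supported compactly
#' supported orthonormal wavelets. The highpass filter is the quadrature
#' mirror of the lowpass: `g[n] = (-1)^n h[L - 1 - n]` (0-based `n`).
#'
#' @param name Wavelet family: one of `"haar"`, `"daubechies4"`,
#'   `"daubechies8"`, `"daubechies10"`, `"coiflet6"`, `"coiflet12"`,
#'   `"coiflet18"` (short forms `"daub8"`, `"coif6"`, ... are accepted).
#' @return An object of class `"filter_bank"`: a list with elements `name`,
#'   `lowpass`, `highpass` and `length` (tap count).
#' @examples
#' fb <- wavelet_filters("daubechies8")
#' fb$length            # 8
#' sum(fb$lowpass^2)    # 1
#' @export
wavelet_filters <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop_config("wavelet name must be a single string")
  key <- .wavelet_aliases[tolower(name)]
  if (is.na(key))
    stop_config(sprintf(
      "unknown wavelet family '%s'; supported: %s",
      name, paste(wavelet_families(), collapse = ", ")))
  h <- .wavelet_taps[[key]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)
  structure(
    list(name = unname(key), lowpass = h, highpass = g, length = L),
    class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %s (length %d)\n", x$name, x$length))
  cat("  lowpass: ", paste(signif(x$lowpass, 6), collapse = " "), "\n")
  cat("  highpass:", paste(signif(x$highpass, 6), collapse = " "), "\n")
  invisible(x)
}

.as_filter_bank <- function(fb) {
  if (inherits(fb, "filter_bank")) fb else wavelet_filters(fb)
}
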