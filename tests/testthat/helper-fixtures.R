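# Shared fixtures and independent oracles.

# A clean fixed-seed synthetic record flattened and delineated.
clean_record <- function(seed = 7, duration = 60, heart_rate = 60, ...) {
  generate_record(synth_config(duration = duration,
                               heart_rate = heart_rate, seed = seed, ...))
}

qrs_recall <- function(peaks, truth, fs, tol_s = 0.04) {
  tol <- round(tol_s * fs)
  mean(vapply(truth, function(p) any(abs(peaks - p) <= tol), logical(1)))
}

false_positives <- function(peaks, truth, fs, tol_s = 0.04) {
  tol <- round(tol_s * fs)
  sum(vapply(peaks, function(p) min(abs(truth - p)) > tol, logical(1)))
}

# Literal transcription of the feature procedure: plain loops, truncated
# mean index gaps, reference voltage at onsets, signed deviation sums to
# the T apex / F point, chord slope, then five-beat block means. Kept
# deliberately naive and separate from the package code path.
oracle_window_features <- function(x, delin, fs, t_window = 0.4) {
  nB <- delin$n_beats
  n <- length(x)
  s <- 0; for (i in 1:nB) s <- s + (delin$peak[i] - delin$onset[i])
  md1 <- trunc(s / nB)
  s <- 0; for (i in 1:nB) s <- s + (delin$offset[i] - delin$peak[i])
  md2 <- trunc(s / nB)
  s <- 0; for (i in 1:nB) s <- s + x[delin$onset[i]]
  ref <- s / nB
  f1 <- c(); f2 <- c(); f3 <- c()
  for (i in 1:nB) {
    p <- delin$peak[i]
    k <- p + md2
    m <- p - md1
    if (m < 1 || k + 1 > n || x[p] == 0) next
    w_end <- k + as.integer(round(t_window * fs))
    if (i < nB) {
      nm <- delin$peak[i + 1] - md1
      if (nm < w_end) w_end <- nm
    }
    if (w_end > n) w_end <- n
    if (w_end <= k) {
      tp <- min(k + 1, n)
      fpnt <- min(k + 1, n)
    } else {
      tp <- k + 1; best <- -1
      for (j in (k + 1):w_end) {
        if (abs(x[j] - ref) > best) { best <- abs(x[j] - ref); tp <- j }
      }
      fpnt <- w_end
      d0 <- x[k] - ref
      for (j in (k + 1):w_end) {
        if ((x[j] - ref) * d0 <= 0) { fpnt <- j; break }
      }
    }
    a <- 0; for (j in k:tp) a <- a + (x[j] - ref)
    b <- 0; for (j in k:fpnt) b <- b + (x[j] - ref)
    f1 <- c(f1, a)
    f2 <- c(f2, b / x[p])
    f3 <- c(f3, (x[k] - x[m]) / (k - m))
  }
  nw <- length(f1) %/% 5
  out <- matrix(NA_real_, nw, 3)
  for (w in seq_len(nw)) {
    s1 <- 0; s2 <- 0; s3 <- 0
    for (j in (5 * w - 4):(5 * w)) {
      s1 <- s1 + f1[j]; s2 <- s2 + f2[j]; s3 <- s3 + f3[j]
    }
    out[w, ] <- c(s1 / 5, s2 / 5, s3 / 5)
  }
  out
}

# spectral power of a real signal at one frequency (DFT projection)
power_at <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  (2 / n * sum(x * cos(2 * pi * f * t)))^2 +
    (2 / n * sum(x * sin(2 * pi * f * t)))^2
}

# fraction of total spectral power above a cutoff frequency
power_frac_above <- function(x, cutoff, fs) {
  sp <- Mod(stats::fft(x - mean(x)))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sum(sp[half & freqs > cutoff]) / sum(sp[half])
}
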