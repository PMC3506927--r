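# Synthetic ECG with ground-truth annotations.
#
# Each beat is a sum of Gaussian bumps (P, Q, R, S, T) around the R time;
# the analytic form gives exact landmark truth for every test. During
# labeled episodes a constant ST level shift is added on [R + 40 ms,
# R + 240 ms] with short cosine ramps. Baseline drift is a sub-0.5 Hz
# sine. This emulates quasi-periodic morphology, controllable ST
# elevation/depression and slow drift; it does not emulate muscle
# artifact, electrode motion, ectopy or rhythm disturbances.

#' Synthetic ECG configuration
#'
#' @param fs Sampling frequency, Hz (default 250).
#' @param duration Record length in seconds (ignored when `n_beats` is
#'   given).
#' @param n_beats Optional exact number of beats to generate.
#' @param heart_rate Mean heart rate, bpm (default 60).
#' @param hr_jitter Fractional uniform jitter on each RR interval
#'   (default 0.05).
#' @param st_deviation ST level shift in mV during episodes; positive =
#'   elevation, negative = depression (default 0).
#' @param episodes Data.frame/matrix with columns `start`, `end`
#'   (seconds) marking ischemic episodes (default none).
#' @param drift_amp Baseline drift amplitude, mV (default 0).
#' @param drift_freq Drift frequency, Hz, below 0.5 (default 0.3).
#' @param noise_sd White measurement noise SD, mV (default 0.01).
#' @param qrs_sign +1 for upward-protruding QRS (default), -1 for
#'   downward.
#' @param waves Named list of wave parameters `c(amp, width, offset)` in
#'   mV / s / s relative to the R time; `width` is the full width at half
#'   maximum of the Gaussian bump. Defaults: R (1.0, 0.020, 0),
#'   Q (-0.15, 0.015, -0.025), S (-0.15, 0.015, 0.025),
#'   P (0.15, 0.060, -0.160), T (0.3, 0.120, 0.300).
#' @param seed Integer seed; fully determines the record.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(fs = 250, duration = 60, n_beats = NULL,
                         heart_rate = 60, hr_jitter = 0.05,
                         st_deviation = 0, episodes = NULL,
                         drift_amp = 0, drift_freq = 0.3,
                         noise_sd = 0.01, qrs_sign = 1,
                         waves = NULL, seed = 1) {
  if (fs <= 0) stop_input("synth_config: fs must be positive")
  if (drift_freq >= 0.5)
    stop_config("synth_config: drift_freq must stay below 0.5 Hz")
  if (!qrs_sign %in% c(-1, 1))
    stop_config("synth_config: qrs_sign must be +1 or -1")
  if (is.null(waves))
    waves <- list(P = c(0.15, 0.060, -0.160),
                  Q = c(-0.15, 0.015, -0.025),
                  R = c(1.00, 0.020, 0.000),
                  S = c(-0.15, 0.015, 0.025),
                  T = c(0.30, 0.120, 0.300))
  if (!is.null(episodes)) {
    episodes <- as.data.frame(episodes)
    names(episodes)[1:2] <- c("start", "end")
    if (any(episodes$end <= episodes$start))
      stop_input("synth_config: episode end must exceed start")
    if (is.null(n_beats) && any(episodes$start < 0 | episodes$end > duration))
      stop_input("synth_config: episodes must lie within the record")
  } else {
    episodes <- data.frame(start = numeric(0), end = numeric(0))
  }
  structure(list(fs = fs, duration = duration, n_beats = n_beats,
                 heart_rate = heart_rate, hr_jitter = hr_jitter,
                 st_deviation = st_deviation, episodes = episodes,
                 drift_amp = drift_amp, drift_freq = drift_freq,
                 noise_sd = noise_sd, qrs_sign = qrs_sign,
                 waves = waves, seed = seed),
            class = "synth_config")
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# cosine-ramped plateau of unit height on [a, b] with ramp time r
.st_plateau <- function(t, a, b, r = 0.01) {
  y <- numeric(length(t))
  inside <- t > a & t < b
  y[inside] <- 1
  up <- t >= a - r & t <= a
  y[up] <- 0.5 * (1 + cos(pi * (a - t[up]) / r))
  dn <- t >= b & t <= b + r
  y[dn] <- 0.5 * (1 + cos(pi * (t[dn] - b) / r))
  y
}

#' Generate an annotated synthetic ECG record
#'
#' @param config A [synth_config()].
#' @return List with `signal` (an [ecg_signal()]), `r_peaks` (1-based
#'   sample indices of the true R times), `r_times` (seconds),
#'   `episodes` (data.frame `start`, `end`) and `config`.
#' @examples
#' rec <- generate_record(synth_config(duration = 20, seed = 42))
#' length(rec$r_peaks)
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    rr_mean <- 60 / config$heart_rate
    # beat times
    if (!is.null(config$n_beats)) {
      nb <- config$n_beats
      rr <- rr_mean * (1 + config$hr_jitter * stats::runif(nb, -1, 1))
      r_times <- 0.5 + cumsum(c(0, rr[-nb]))
      duration <- r_times[nb] + 1
    } else {
      duration <- config$duration
      r_times <- numeric(0)
      t_cur <- 0.5
      while (t_cur < duration - 0.6) {
        r_times <- c(r_times, t_cur)
        t_cur <- t_cur +
          rr_mean * (1 + config$hr_jitter * stats::runif(1, -1, 1))
      }
    }
    n <- as.integer(round(duration * config$fs))
    t <- (seq_len(n) - 1) / config$fs
    x <- numeric(n)
    in_episode <- function(tb) {
      nrow(config$episodes) > 0 &&
        any(tb >= config$episodes$start & tb <= config$episodes$end)
    }
    for (tb in r_times) {
      lo <- max(1L, as.integer(floor((tb - 0.45) * config$fs)))
      hi <- min(n, as.integer(ceiling((tb + 0.65) * config$fs)))
      tt <- t[lo:hi]
      seg <- numeric(length(tt))
      for (wn in names(config$waves)) {
        w <- config$waves[[wn]]
        amp <- w[1]
        if (wn %in% c("Q", "R", "S")) amp <- amp * config$qrs_sign
        sigma <- w[2] / (2 * sqrt(2 * log(2)))   # width is FWHM
        seg <- seg + amp * exp(-(tt - tb - w[3])^2 / (2 * sigma^2))
      }
      if (config$st_deviation != 0 && in_episode(tb))
        seg <- seg + config$st_deviation *
          .st_plateau(tt, tb + 0.04, tb + 0.24)
      x[lo:hi] <- x[lo:hi] + seg
    }
    if (config$drift_amp != 0)
      x <- x + config$drift_amp * sin(2 * pi * config$drift_freq * t)
    if (config$noise_sd > 0)
      x <- x + stats::rnorm(n, 0, config$noise_sd)
    r_peaks <- as.integer(round(r_times * config$fs)) + 1L
    list(signal = ecg_signal(x, config$fs), r_peaks = r_peaks,
         r_times = r_times, episodes = config$episodes, config = config)
  })
}

#' Add deterministic baseline-plus-powerline noise
#'
#' Adds `s * a * (sin(b * t) + 0.5 * cos(2 pi 60 t))` to the record, where
#' `s` is the population standard deviation of the input samples, `a` an
#' amplification factor, `b` the angular frequency (rad/s) of the added
#' wandering baseline and `t` the 0-based sample time in seconds. The
#' study grid is `a` in 0.1..1.0 (step 0.1) with `b` in {2, 4, 6}.
#'
#' @param sig An [ecg_signal()].
#' @param a Amplification factor (0 returns the input unchanged).
#' @param b Angular frequency of the added baseline, rad/s.
#' @return A noisy [ecg_signal()].
#' @export
add_noise <- function(sig, a, b) {
  x <- sig$samples
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum(x^2) / n - m^2)
  t0 <- (seq_len(n) - 1) / sig$fs
  ecg_signal(x + s * a * (sin(b * t0) + 0.5 * cos(2 * pi * 60 * t0)),
             sig$fs)
}
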