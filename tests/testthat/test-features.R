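fake_delin <- function(onset, peak, offset) {
  structure(list(onset = as.integer(onset), peak = as.integer(peak),
                 offset = as.integer(offset),
                 polarity = rep("up", length(peak)),
                 n_beats = length(peak)),
            class = "qrs_delineation")
}

test_that("the feature context takes truncated mean gaps and onset voltage", {
  x <- numeric(40); x[11] <- 0.2
  ctx <- compute_context(ecg_signal(x, 250), fake_delin(11, 15, 21))
  expect_equal(ctx$ref_voltage, 0.2)
  expect_identical(ctx$mean_idx_diff_1, 4)
  expect_identical(ctx$mean_idx_diff_2, 6)
  # 10/3 truncates to 3
  d <- fake_delin(c(1, 11, 21), c(4, 15, 24), c(8, 19, 28))
  ctx <- compute_context(ecg_signal(numeric(40), 250), d)
  expect_identical(ctx$mean_idx_diff_1, 3)
  expect_equal(ctx$ref_voltage, 0)
  expect_error(compute_context(ecg_signal(numeric(4), 250),
                               fake_delin(integer(0), integer(0),
                                          integer(0))),
               class = "stseg_input_error")
})

test_that("the T apex is the largest absolute deviation after the offset proxy", {
  fs <- 250
  x <- numeric(200)
  k <- 50L
  x[k + 75] <- 0.4          # bump 300 ms after the proxy
  sig <- ecg_signal(x, fs)
  expect_identical(find_t_peak(sig, k, 0), k + 75L)
  # flat segment: earliest index wins
  expect_identical(find_t_peak(ecg_signal(numeric(200), fs), k, 0), k + 1L)
  # depressed ST with a negative T is found through the absolute value
  x2 <- numeric(200); x2[k + 60] <- -0.5
  expect_identical(find_t_peak(ecg_signal(x2, fs), k, 0), k + 60L)
  # the window clips at the next beat's onset proxy
  x3 <- numeric(200); x3[k + 90] <- 1
  expect_identical(find_t_peak(ecg_signal(x3, fs), k, 0, next_m = k + 20L),
                   k + 1L)
})

test_that("the F point is the first return to the reference level", {
  fs <- 250
  k <- 50L
  x <- numeric(200); x[k] <- 2; x[k + 1] <- 2; x[k + 2] <- 1; x[k + 3] <- -1
  expect_identical(find_f_point(ecg_signal(x, fs), k, 0), k + 3L)
  # already at the reference: immediate touch
  expect_identical(find_f_point(ecg_signal(numeric(200), fs), k, 0), k + 1L)
  # never returns inside the window: falls back to the window end
  x2 <- numeric(200) + 1
  expect_identical(find_f_point(ecg_signal(x2, fs), k, 0),
                   k + as.integer(round(0.4 * fs)))
})

test_that("beat features implement the deviation sums and the chord slope", {
  fs <- 250
  # one beat; gaps of 4 and 6 give proxies m = peak - 4, k = peak + 6
  x <- numeric(400)
  p <- 100L
  x[p] <- 4                       # R peak voltage
  k <- p + 6L; m <- p - 4L
  x[k:(k + 2)] <- c(1, 2, 3)      # deviations up to the apex at k+2
  d <- fake_delin(p - 4L, p, p + 6L)
  bf <- beat_features(ecg_signal(x, fs), d)
  expect_equal(bf$beats$f1, 6)                 # 1 + 2 + 3
  expect_identical(bf$beats$t_peak, k + 2L)
  # f2 terminates at the first sign change and divides by the peak voltage
  expect_identical(bf$beats$f_point, k + 3L)   # first zero after [1,2,3]
  expect_equal(bf$beats$f2, 6 / 4)
  # the chord here rises from 0 at m to 1 at k over 10 samples
  expect_equal(bf$beats$f3, (x[k] - x[m]) / (k - m))
  # flat chord -> zero slope
  x2 <- numeric(400); x2[p] <- 4
  bf2 <- beat_features(ecg_signal(x2, fs), d)
  expect_equal(bf2$beats$f3, 0)
})

test_that("zero peak voltage drops the beat with a warning", {
  d <- fake_delin(c(6, 26), c(10, 30), c(16, 36))
  x <- numeric(400); x[10] <- 2   # second beat peak voltage is 0
  expect_warning(bf <- beat_features(ecg_signal(x, 250), d), "dropped")
  expect_equal(nrow(bf$beats), 1)
})

test_that("window averaging takes non-overlapping blocks of five", {
  b <- data.frame(peak = 1:10, onset_proxy = 1:10, offset_proxy = 1:10,
                  t_peak = 1:10, f_point = 1:10,
                  f1 = as.numeric(1:10), f2 = 0, f3 = 0)
  w <- window_features(b)
  expect_equal(nrow(w), 2)
  expect_equal(w$f1, c(3, 8))
  # a remainder below five is discarded
  expect_equal(nrow(window_features(b[1:7, ])), 1)
  expect_equal(nrow(window_features(b[1:4, ])), 0)
  # five identical beats average to themselves
  w5 <- window_features(b[rep(2, 5), ])
  expect_equal(w5$f1, 2)
})

test_that("features agree bit for bit with a loop-literal transcription", {
  for (seed in 1:10) {
    rec <- clean_record(seed = seed, duration = 30,
                        heart_rate = 55 + 5 * (seed %% 5))
    fecg <- remove_baseline(rec$signal)
    q <- detect_qrs(fecg)
    bf <- beat_features(fecg, q$delineation)
    win <- window_features(bf$beats)
    oracle <- oracle_window_features(fecg$samples, q$delineation, fecg$fs)
    expect_identical(win$f1, oracle[, 1])
    expect_identical(win$f2, oracle[, 2])
    expect_identical(win$f3, oracle[, 3])
  }
})

test_that("a constant voltage offset leaves f1 and f3 unchanged", {
  rec <- clean_record(seed = 31, duration = 30)
  fecg <- remove_baseline(rec$signal)
  q <- detect_qrs(fecg)
  bf <- beat_features(fecg, q$delineation)
  shifted <- ecg_signal(fecg$samples + 0.37, fecg$fs)
  bf2 <- beat_features(shifted, q$delineation)
  expect_equal(bf2$beats$f1, bf$beats$f1, tolerance = 1e-9)
  expect_equal(bf2$beats$f3, bf$beats$f3, tolerance = 1e-12)
  # f2 changes only through its peak-voltage denominator
  p <- bf$beats$peak
  expect_equal(bf2$beats$f2,
               bf$beats$f2 * fecg$samples[p] / (fecg$samples[p] + 0.37),
               tolerance = 1e-9)
})

test_that("ST elevation and depression separate f1 in the injected direction", {
  mk <- function(dev) {
    rec <- generate_record(synth_config(
      duration = 120, heart_rate = 70, st_deviation = dev,
      episodes = data.frame(start = 30, end = 90), seed = 33))
    fecg <- remove_baseline(rec$signal)
    feats <- extract_features(fecg)
    ds <- build_dataset(feats, rec$episodes, 250, trim = 5)
    c(mean(ds$f1[ds$label == "S"]), mean(ds$f1[ds$label == "N"]))
  }
  up <- mk(0.2)
  expect_gt(up[1], up[2])
  dn <- mk(-0.2)
  expect_lt(dn[1], dn[2])
})
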