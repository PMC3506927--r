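# stseg — ischemic ST-episode detection in ECG

`stseg` detects ischemic ST episodes — intervals where the ST segment of
the electrocardiogram is displaced above or below the isoelectric line by
myocardial ischemia — on single-channel ECG. It is aimed at biomedical
signal-processing researchers who need a transparent, fully scriptable
reference chain: every stage is an exported R function, and a synthetic
ECG generator with exact ground truth makes the whole pipeline testable
without any database download.

The chain:

1. **Baseline wander removal.** A periodized orthogonal DWT (Haar,
   Daubechies 4/8/10, Coiflet 6/12/18) decomposes the record to depth
   `k = ⌈log₂ fs⌉`, so the approximation band `(0, fs/2^{k+1})` lies
   below 0.5 Hz; zeroing all detail bands and reconstructing gives the
   baseline, and `fecg = ecg − baseline` the flattened signal.
2. **QRS detection.** Each detail scale `j` is scored by
   `score_j = Σ fecg·pulse_j / Σ|pulse_j|`, where `pulse_j` is the
   single-band reconstruction; the scale with the largest drop
   `score_j − score_{j+1}` (`j ∈ [2, k−2]`) is QRS-dominant. Peaks are
   thresholded local maxima of the needle signal `fecg·pulse`; onsets
   and offsets come from a two-direction-change walk away from each
   peak.
3. **Features.** Relative to the effective zero voltage (mean `fecg` at
   QRS onsets): `f1` the signed ST/T area from the QRS offset proxy to
   the T apex, `f2` the signed area to the first return-to-reference
   point normalized by R amplitude, `f3` the QRS chord slope — averaged
   over five-beat windows.
4. **Classification.** A product-bandwidth kernel density Bayes
   classifier; bandwidths are set automatically to
   `0.5 × mean |pairwise component difference|` per class, so no
   numerical parameter needs hand-tuning. Six kernels are supported;
   an RBF-SVM comparator (`exp(−‖x−x′‖²/3)`, C swept) is included.
   Sensitivity/specificity are window-level; an episode is detected on
   a strict ischemic majority of its windows.

See `vignettes/st-episode-detection.Rmd` for the model details and
design rationale.

## Worked example

```r
library(stseg)

rec <- generate_record(synth_config(
  duration = 180, heart_rate = 70, st_deviation = -0.15,   # ST depression
  episodes = data.frame(start = 60, end = 120),
  drift_amp = 0.5, seed = 42))

fecg <- remove_baseline(rec$signal)          # Daubechies8, depth 8 at 250 Hz
q    <- detect_qrs(fecg)
q$selection
#> <scale_selection> chosen scale 4 of depth 8
#>       1       2       3       4       5       6       7
#> 0.01065 0.06927 0.20970 0.16990 0.09554 0.09732 0.05191

feats <- beat_features(fecg, q$delineation)
win   <- window_features(feats$beats)
ds    <- build_dataset(list(windows = win, beats = feats$beats),
                       rec$episodes, fs = 250)
table(ds$label)
#> N S
#> 8 8

sp <- split_windows(ds, 1/3, seed = 42)
m  <- kde_fit(as.matrix(sp$train[sp$train$label == "S", c("f1","f2","f3")]),
              as.matrix(sp$train[sp$train$label == "N", c("f1","f2","f3")]))
m
#> <kde_model> kernel gaussian, factor 0.5; n_N = 2, n_S = 2
#>   b(N): 0.646 0.8801 0.0001905  b(S): 0.4877 1.475 0.0009434

pred <- kde_classify(m, as.matrix(sp$test[, c("f1","f2","f3")]))
confusion(pred, sp$test$label)
#> Se 1.000  Sp 1.000  (TP 6 FN 0 FP 0 TN 6)
```

The scale scores peak at scale 3–4 (the 8–31 Hz QRS band at 250 Hz) and
drop beyond it, so scale 4 is chosen. The depressed-ST windows separate
cleanly from normal ones in the `(f1, f2, f3)` space, and the
automatically chosen bandwidths span the three orders of magnitude
between the area features and the slope feature without any manual
normalization.

A command-line interface wraps the same functions
(`inst/cli/stseg simulate | preprocess | qrs | features | fit-kde |
classify | evaluate`), reading and writing CSV/JSON.

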