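Package: stseg
Title: Ischemic ST-Episode Detection in ECG by Wavelets and Kernel Density Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end detection of ischemic ST episodes in single-channel
    electrocardiograms. Removes sub-0.5 Hz baseline wander with an orthogonal
    discrete wavelet transform, locates and delineates QRS complexes from a
    scale-scored single-band reconstruction, extracts three ST-morphology
    features averaged over five-beat windows, and classifies windows with a
    product-bandwidth kernel density estimator whose bandwidths are set
    automatically from mean pairwise feature differences. A soft-margin
    RBF support vector machine comparator, a synthetic ECG generator with
    labeled ST-deviation episodes, evaluation utilities (sensitivity,
    specificity, episode-majority detection) and a command-line interface
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
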