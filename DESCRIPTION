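Package: rhythmoscan
Title: Detecting Rhythmicity in Auditory Perceptual Judgements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether auditory perceptual performance fluctuates
    rhythmically with the delay between a reference event (background-noise
    onset) and a monaural target. Implements signal-detection metrics
    (d-prime, criterion) over delay bins, three calibrated statistical tests
    for periodicity (amplitude spectra against AR(1) surrogate distributions;
    vector-strength linear models on binned and single-trial data with
    permutation nulls), simulation-based calibration of first-level
    significance thresholds to a target family-wise false-positive rate,
    bootstrap prevalence of significant effects across participant resamples,
    and paired condition contrasts (dual task, pupil size, fixation
    stability). A synthetic-data module generates experiment designs,
    rhythmically modulated observers, adaptive staircases, a linear-model
    calibration generator, and gaze/pupil traces so that every stage of the
    pipeline can be exercised without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
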