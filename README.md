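# rhythmoscan

Tools for asking whether auditory perceptual performance is *rhythmic*: does
sensitivity, response bias or reaction time oscillate as a function of the
delay between a reference event (the onset of a background noise) and a
brief monaural target? The package is aimed at psychophysicists analysing
trial tables from delay-sampling paradigms — and at methodologists who want
the statistical machinery for such claims with its false-positive rate
under control.

## What it implements

Trials carry a target delay t ∈ [0.3, 1.5] s after noise onset, re-referenced
to the uncertainty window as t′ ∈ [0, 1.2] s. Per participant, delays are
binned into twenty 60 ms bins and summarised as d′ = z(H) − z(FA),
c = −(z(H) + z(FA))/2 (log-linear corrected) and mean √RT. Three calibrated
tests then probe periodicity across a grid of frequencies:

* **Spectra** — amplitude spectra of the linearly detrended, zero-padded
  binned series (1.05–8.1 Hz, ~0.2 Hz steps), compared against spectra of
  AR(1) surrogate series fit per participant; group inference by percentile
  bootstrap of participant-averaged spectra.
* **Binned** — linear model per binned series with offset, linear, u/v
  (0.5 Hz half-cycle) and sin/cos predictors at each frequency
  (1.2–8 Hz, 49 frequencies); the statistic is the vector strength
  (β²_sin + β²_cos)/2, tested against a within-participant shuffle null.
* **Trials** — the same model on single-trial correctness
  (binomial/logit) or √RT (gaussian) at delays without binning
  (1.2–12 Hz, 54 frequencies).

Because the approaches differ in how p-values co-vary across frequencies,
first-level thresholds are **calibrated by simulation** to a common
family-wise false-positive rate (target 0.05) on null data from the
generator β₀ + β₁t + β₂·uv(t) + β₃sin(2π·4t) + β₄cos(2π·4t) + ε, and
validated on held-out null runs. Bootstrap resampling of participants gives
the **prevalence** of significant effects across cohort variation; paired
contrasts (dual task, pupil-size and fixation-stability median splits)
compare vector-strength curves between conditions with BH-corrected paired
t-tests. A synthetic-data module (designs, rhythmic SDT observers,
staircases, eye traces) makes the entire pipeline runnable and testable
without any experimental data.

## Worked example

Simulate a cohort of eight observers whose d′ oscillates at 4 Hz
(amplitude 0.8 around a baseline of 1.5), then scan the binned metrics:

```r
library(rhythmoscan)

obs <- observer_params(d0 = 1.5,
                       rhythm = rhythm_component("dprime", freq_hz = 4,
                                                 amplitude = 0.8))
cohort <- do.call(rbind, lapply(1:8, function(i) {
  d <- generate_design(design_config("exp1", seed = 7 + i),
                       participant_id = sprintf("s%02d", i))
  simulate_observer(d, obs, seed = 100 + i)
}))
cohort <- reference_delays(transform_rt(filter_outliers(trial_table(cohort))))

binned <- compute_binned_metrics(cohort, ear_sets = "both")
scan <- rhythm_scan(binned, "binned", metric = "dprime",
                    n_perm = 1000, seed = 9)
scan
#> rhythm_scan: binned approach, metric dprime, ear_set both
#>   8 participants, 49 frequencies (1.20-8.00 Hz), 1000 surrogates
#>   min p = 0.000999 at 3.50 Hz
```

The minimum group p-value sits at the permutation floor 1/1001 ≈ 0.000999
on a plateau of frequencies around the injected rhythm (3.5–4.4 Hz all
reach the floor; the group vector strength peaks at exactly 4 Hz). How
reproducible is that effect across cohorts drawn from these eight
participants?

```r
prev <- bootstrap_prevalence(scan, threshold = 0.001, n_boot = 2000,
                             seed = 10)
prev$prevalence[which.min(abs(prev$freqs_hz - 4))]
#> [1] 1
```

Every bootstrap resample of the cohort is significant near 4 Hz: with an
effect this strong, prevalence saturates at 1. Weaker modulations yield
intermediate prevalence — the quantity to report alongside the fixed-sample
p-value.

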