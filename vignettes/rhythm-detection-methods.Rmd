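---
title: "Detecting rhythmicity in perceptual judgements: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rhythmicity in perceptual judgements: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmoscan)
```

## The scientific problem

A long-standing hypothesis holds that perception operates in cycles: the
probability of detecting or discriminating a stimulus waxes and wanes
quasi-periodically relative to a reference event. In the paradigms this
package targets, listeners judge a brief monaural target tone embedded in
binaural background noise, with the target occurring at a random delay of
0.3 to 1.5 s after noise onset. If perception is rhythmic, behavioural
metrics — sensitivity (d′), response bias (criterion c), reaction time —
should oscillate as a function of that delay.

Testing this is statistically delicate. Delay is a continuous covariate;
binning it allows signal-detection metrics but invites binning artefacts;
spectral statistics on short (20-point) series have coarse, correlated
frequency resolution; and scanning many candidate frequencies inflates the
family-wise false-positive rate in ways that differ between analysis
strategies. The package therefore implements three complementary tests and a
simulation-based calibration that equates their specificity, so that their
outcomes can be compared on an equal footing.

## Data model

Trials are rows of a fixed-schema table (`trial_table()`): participant,
experiment (`exp1`–`exp4`), block, trial, ear (`L`/`R`), condition
(`f1`/`f2`), target delay, response (`opt1`/`opt2`/`none`), correctness,
reaction time, the adaptive stimulus parameter, and dual-task flags.
Preparation is a fixed sequence:

1. `filter_outliers()` removes trials with reaction times outside
   [0.15 s, 2.5 s], missed responses, and presses of non-task keys. It is
   the single filtering entry point, applied globally before any metric is
   computed (whether the original analyses filtered before or after binning
   is not documented; doing it first keeps every downstream quantity
   consistent).
2. `transform_rt()` adds `rt_sqrt`; all reaction-time analyses operate on
   the square-root scale, which symmetrises the right-skewed RT
   distribution.
3. `reference_delays()` maps delays to the window-relative axis
   `delay_ref_s = delay_s - 0.3` spanning 0–1.2 s.

`compute_binned_metrics()` then bins `delay_ref_s` into twenty 60 ms bins
(half-open, with the final bin closed at 1.2 s so the window is covered
exactly) and computes per bin, per ear and for both ears pooled: d′, c and
mean √RT. Condition `f1` is treated as the signal, and hit/false-alarm
rates use the log-linear (add 0.5 / add 1) correction, which is defined for
every cell count and keeps extreme-rate bins finite. Bins missing a
condition yield `NA` and are excluded listwise downstream (with ~19 trials
per bin per ear this is rare but possible; interpolation is used only
inside the spectral detrending step, where a fixed-length series is
required).

## The three statistical approaches

All three share one inferential skeleton: a per-participant statistic per
frequency, a per-participant surrogate distribution of that statistic under
a null, index-wise averaging of surrogates across participants to form a
group-level null, and an add-one percentile p-value
`p = (1 + #{group surrogate >= actual}) / (1 + n)` at each frequency. No
assumption is made that participants share a phase — only that the sample
oscillates at a common frequency.

**Spectra** (`spectra_test()`). Each binned series is linearly detrended,
zero-padded by 30 points on each side (length 80, giving a 0.208 Hz grid at
the 16.7 Hz bin rate) and Fourier transformed; the statistic is the DFT
amplitude at the 35 grid frequencies spanning nominally 1.05–8.1 Hz (bins
5–39, 1.042–8.125 Hz — the printed band endpoints do not fall on the padded
grid, so the package takes the DFT bins the stated band rounds to).
Amplitude rather than power is used; the choice cancels in a percentile
test because actual and surrogate spectra pass through the identical
transform. No taper is applied (detrend + pad only). The null preserves
autocorrelation but destroys periodicity: an AR(1) model is fit to each
series by least squares (`fit_ar1()`; coefficients outside the stationarity
region on these short series are clipped to ±0.99 with a warning), and
surrogate series are simulated from it with gaussian innovations
(`simulate_ar_surrogates()`). The nominal 2000-step burn-in is applied in
closed form — after k steps from a zero state the AR(1) state is exactly
N(0, s²(1−a^{2k})/(1−a²)) — so only the 20 output steps are iterated; this
is distributionally identical to literal burn-in and orders of magnitude
faster.

**Binned** (`rhythm_scan(..., approach = "binned")`). Each binned series is
modelled by a gaussian linear model with five predictors
(`build_design()`): an intercept, a linear delay term, a u/v-shaped term,
and the sine and cosine of the tested frequency. The u/v term is realised
as `cos(2π·0.5·(t − 0.6))` — a half cycle at 0.5 Hz symmetric about the
window midpoint, absorbing a slow rise-and-fall of performance across the
1.2 s target-uncertainty window; the phase convention (symmetry about
0.6 s) is a package choice and is configurable. The statistic is the
*vector strength* of the rhythmic pair, `(β_sin² + β_cos²)/2` — phase
invariant and quadratic in modulation amplitude. The null shuffles the
assignment between bins and metric values within participant and refits.
Tested frequencies: 1.2–4 Hz in 0.1 Hz steps and 4.2–8 Hz in 0.2 Hz steps
(49 frequencies).

**Trials** (`rhythm_scan(..., approach = "trials")`). The same linear model
evaluated at single-trial delays: binomial with logit link for trial
correctness, gaussian for single-trial √RT (the square-root scale is used
for consistency with the binned RT metric). The unbinned axis supports a
higher maximum frequency: the binned grid extended by 8.8–12 Hz in 0.8 Hz
steps (54 frequencies). The null shuffles the delay–outcome assignment
within participant. Binomial refits that fail to converge (separation can
occur during permutation refits) fall back to a small ridge penalty
(λ = 10⁻³) so a null distribution is never aborted; such fits are flagged.

Predictors are left unstandardised so betas keep interpretable units;
vector strengths are only ever compared like for like (same metric, family
and design), where the scaling is internally consistent.

### Numerical fast path

Within a participant, one set of shuffles is shared across all grid
frequencies. Each frequency's marginal null is unchanged, while the joint
null across frequencies retains its dependence — exactly the dependence the
family-wise calibration (below) relies on — and the full grid can be
refit with one matrix product per participant: by the Frisch–Waugh theorem
the sine/cosine betas equal those from regressing the residualised outcome
on the residualised sine/cosine pair, and the nuisance block (intercept,
linear, u/v) is common to all frequencies, so each frequency collapses to a
closed-form 2×2 system. The gaussian path is tested against `lm.fit()` to
10⁻¹⁰. Permutation indices are generated by a small C++ kernel driven by
R's RNG stream, so `set.seed()` semantics are preserved; per-participant
streams are derived deterministically from one master seed.

## Calibrating the family-wise false-positive rate

Because the three approaches differ in sensitivity and in how their
per-frequency p-values co-vary, a fixed first-level cutoff (say 0.05) would
give them different family-wise false-positive rates across the grid. The
package therefore selects each approach's first-level threshold on
simulated null data (`run_calibration()`, `select_threshold()`):

* Generator: 25 participants × 700 trials; per participant, betas drawn
  once from gaussian priors — offset (1, 0.1), linear slope (0.1, 0.1), u/v
  (0.1, 0.1), sine and cosine at 4 Hz (0.2, 0.1), as (mean, SD) — and
  `y = β₀ + β₁t + β₂·uv(t) + β₃·sin(2π·4t) + β₄·cos(2π·4t) + ε` with t
  uniform on [0, 1.2] and ε gaussian. Null runs zero the rhythmic betas and
  use noise SDs 2, 4, 6; effect runs keep them and use SDs 2–8.
* Simulated outcomes are continuous, so all three approaches analyse them
  with the gaussian family (whether the original calibration used a
  binomial model for the trials approach is not stated; the gaussian
  identity family matches the "normally distributed data" the generator
  produces).
* The threshold per approach is the cutoff whose family-wise rate — the
  fraction of null runs with min-over-frequency p at or below it, pooled
  across the null noise SDs — matches the target (0.05, and separately
  0.01). Because permutation p-values are discrete, the achievable rates
  form atoms (about 0.015 apart at the shipped resolution):
  `select_threshold()` offers the strictly-below reading
  (`rule = "conservative"`, the default, which undershoots the target by up
  to one atom) and the `rule = "nearest"` reading used by the shipped
  calibration protocol, which centres the realised rate on the target — at
  full-count resolution the two coincide. Specificity is then validated on
  freshly seeded null runs, which avoids the optimism of measuring on the
  selection runs (`evaluate_operating_characteristics()`); sensitivity per
  noise SD is the fraction of effect runs with a significant frequency
  anywhere, and within ±0.3 Hz of 4 Hz.

### Resolution of the permutation null

Add-one permutation p-values are discrete with floor `1/(n_perm + 1)`.
With 10,000 permutations the floor is negligible; at the package's
desk-scale default of 500 it is not: across ~50 tested frequencies the null
probability that *some* frequency sits at the floor measures about 0.03
(spectra, binned) to 0.07 (trials) — in the latter case no cutoff with
family-wise rate ≤ 0.05 exists at all. The package therefore separates the
number of per-participant permutations (`n_perm`) from the number of
group-level surrogates (`n_group`): when `n_group > n_perm`, additional
group surrogate means are formed by seeded re-pairing of per-participant
surrogate statistics across participants. Under the null every
per-participant surrogate is an independent draw of the same statistic, so
each re-paired group mean has exactly the distribution of an index-wise
one; re-pairing only refines the percentile resolution to
`1/(n_group + 1)`. The calibration and acceptance paths use `n_perm = 500`,
`n_group = 2000`; the default everywhere else remains plain index-wise
pairing.

Problem sizes used by the shipped calibration (300 null runs per noise SD
for selection, 300 per SD held out for validation, 500
permutations/surrogates per participant, 2000 group surrogates) were chosen
so a full calibration completes on a single desktop core in minutes while
keeping the Monte-Carlo standard error of the realised family-wise rate
near 0.01; the full-scale settings (1000 runs, 10,000 permutations) are
plain arguments away.

## Prevalence, co-occurrence and condition contrasts

`bootstrap_prevalence()` quantifies how reproducible a significant effect
is across cohort composition: participants are resampled with replacement
(sample size = pool size), the group statistic and group surrogate
distribution are rebuilt from the drawn participants' precomputed
statistics, and significance at the calibrated threshold is re-evaluated
per frequency; prevalence is the fraction of resamples significant. Nothing
is refit inside the bootstrap — under participant exchangeability,
resampling rows of the precomputed actual/surrogate statistics is
equivalent, and the equivalence is verified against an explicit resampling
loop in the test suite. `average_prevalence()` averages curves across
experiments; `band_flags()` plus `cooccurrence_correlation()` correlate the
presence of effects in two ear-frequency bands across the same bootstrap
draws (the reported two-sided p uses the t-approximation and is
descriptive: the flags share bootstrap draws, so this is a within-resample
association, not an independent-samples test).

`contrast_conditions()` compares two paired conditions (dual task vs
single task; median-split halves by pupil size or fixation stability):
per participant and condition it computes binned-approach vector-strength
curves, contrasts them with per-frequency paired t-tests, corrects across
the frequency grid (only) with Benjamini–Hochberg, and bootstraps
participants for the prevalence of significant differences.

Eye metrics (`compute_eye_metrics()`) follow an all-or-none epoch rule:
any invalid sample (blink, missing, gaze beyond ±14° on either axis) in
the −0.4 to +1.5 s epoch discards the trial. Pupil size is z-scored within
participant over retained epochs (a constant pupil yields z = 0 with a
warning), and both trial metrics — mean pupil z and fixation stability,
the mean of the SDs of horizontal and vertical gaze — are computed from
noise onset to the target. Median splits assign ties to the low half;
participants need 400 trials per half (the "400 trials per split"
inclusion rule is ambiguous between per-half and total; per-half is the
stricter reading and is what `median_split()` enforces), and participants
with fewer than 600 valid trials are flagged for exclusion upstream.

## The synthetic-data module

Every stage above is testable without data because the package generates
its own:

* `generate_design()` reproduces the four designs exactly: 8 × 190 trials
  (380 per ear × condition) for the main experiments, 16 × 130 with the
  dual task in half the blocks (260 per ear × condition × task) for the
  dual-task experiment, uniform delays, and dot changes on half the
  dual-task trials at a time uniform between 0.1 s after noise onset and
  the target.
* `simulate_observer()` is an equal-variance gaussian SDT observer with
  symmetric evidence placement (±d′/2 around the criterion) — the standard
  convention, since the original analyses never commit to an observer
  model. Sensitivity, criterion and √RT each accept additive sinusoidal
  modulations (per ear or both), lapses respond uniformly, and RTs are
  generated on the √ scale and squared so the analysis-side transform
  recovers approximately gaussian residuals.
* `run_staircase()` / `adapt_difficulty()` implement the 3-down-1-up
  threshold procedure (four interleaved tracks; threshold = mean of the
  last five reversals) and the 69–80% / 4% running-accuracy controller.
  The step schedule (4 dB, halved at early reversals to a 1 dB floor, stop
  after 10 reversals) is a package choice — only the "last five reversals"
  rule is fixed by the source paradigms. The test suite verifies the rule's
  long-run accuracy sits near the theoretical 79.4% convergence point and
  that the controller keeps a stationary observer inside its band.
* `simulate_calibration_dataset()` is the calibration generator above;
  `simulate_eye_traces()` produces gaze jitter (per-trial SD), optional
  drift, a slow AR(1) pupil process and Poisson blinks.

What the generators deliberately do *not* emulate: learning and fatigue
(beyond a linear RT drift), serial dependence between trials, saccade
sequences or pupil light responses, and any coupling between the eye
metrics and behaviour. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its stated
assumptions — not that real data satisfy those assumptions.

## Known limitations

* The AR(1) surrogate null is fit per participant on 20 points; the
  coefficient estimate carries the classic −1/n small-sample bias, which
  slightly reddens the surrogate spectra. The calibration step absorbs any
  resulting miscalibration of first-level p-values.
* Binomial single-trial scans refit a GLM per permutation and frequency;
  they are orders of magnitude slower than the gaussian fast path and are
  the right tool only at moderate permutation counts (or full-scale
  patience).
* The co-occurrence correlation inherits the dependence structure of the
  bootstrap; its p-value is descriptive.
* Thresholds are calibrated per approach, pooled across metrics and ear
  sets (whether the original study used metric-specific thresholds is not
  stated; a single per-approach threshold is the simpler reading and is
  what `select_threshold()` returns).
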