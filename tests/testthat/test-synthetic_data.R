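test_that("generated designs are balanced and delays uniform", {
  d1 <- generate_design(design_config("exp1", seed = 11))
  counts <- table(d1$ear, d1$condition)
  expect_true(all(counts == 380))
  d4 <- generate_design(design_config("exp4", seed = 12))
  counts4 <- table(d4$ear, d4$condition, d4$dual_task)
  expect_true(all(counts4 == 260))
  # dot changes: half the dual-task trials, timed between 0.1 s and target
  dual <- d4[d4$dual_task, ]
  expect_equal(sum(dual$dot_change), nrow(dual) %/% 2)
  chg <- dual[dual$dot_change, ]
  expect_true(all(chg$dot_time_s >= 0.1 & chg$dot_time_s <= chg$delay_s))
  # uniformity of delays over [0.3, 1.5]
  ks <- suppressWarnings(ks.test(d1$delay_s, "punif", 0.3, 1.5))
  expect_gt(ks$p.value, 0.001)
  # reproducible under a fixed seed, different under another
  d1b <- generate_design(design_config("exp1", seed = 11))
  expect_identical(d1$delay_s, d1b$delay_s)
  d1c <- generate_design(design_config("exp1", seed = 99))
  expect_false(identical(d1$delay_s, d1c$delay_s))
  expect_error(design_config("exp1", n_blocks = 3, trials_per_block = 5),
               "divisible")
})

test_that("simulated observers reproduce their generating SDT parameters", {
  cfg <- design_config("exp1", n_blocks = 10, trials_per_block = 1000,
                       seed = 21)
  d <- generate_design(cfg)
  # chance level when d0 = 0
  t0 <- simulate_observer(d, observer_params(d0 = 0, c0 = 0), seed = 1)
  expect_lt(abs(mean(t0$correct) - 0.5), 3 * sqrt(0.25 / nrow(t0)))
  # d-prime recovery when d0 = 1.5
  t1 <- simulate_observer(d, observer_params(d0 = 1.5, c0 = 0), seed = 2)
  sdt <- compute_sdt(sum(t1$condition == "f1" & t1$response == "opt1"),
                     sum(t1$condition == "f1"),
                     sum(t1$condition == "f2" & t1$response == "opt1"),
                     sum(t1$condition == "f2"))
  expect_lt(abs(sdt$dprime - 1.5), 0.1)
  expect_lt(abs(sdt$bias), 0.05)
})

test_that("swapping condition labels flips the criterion, not d-prime", {
  cfg <- design_config("exp1", n_blocks = 4, trials_per_block = 500,
                       seed = 31)
  d <- generate_design(cfg)
  tab <- simulate_observer(d, observer_params(d0 = 1.2, c0 = 0.4), seed = 3)
  sdt <- compute_sdt(sum(tab$condition == "f1" & tab$response == "opt1"),
                     sum(tab$condition == "f1"),
                     sum(tab$condition == "f2" & tab$response == "opt1"),
                     sum(tab$condition == "f2"))
  # relabel f1<->f2 and opt1<->opt2: hits become correct rejections
  sdt_sw <- compute_sdt(sum(tab$condition == "f2" & tab$response == "opt2"),
                        sum(tab$condition == "f2"),
                        sum(tab$condition == "f1" & tab$response == "opt2"),
                        sum(tab$condition == "f1"))
  expect_equal(sdt_sw$dprime, sdt$dprime, tolerance = 1e-12)
  expect_equal(sdt_sw$bias, -sdt$bias, tolerance = 1e-12)
})

test_that("a binned d-prime rhythm surfaces at the injected frequency", {
  params <- observer_params(d0 = 1.5,
                            rhythm = rhythm_component("dprime", 4, 1))
  tab <- sim_cohort(1, params, seed = 41)
  bm <- compute_binned_metrics(tab, ear_sets = "both")
  series <- bm$dprime
  spec <- compute_spectrum(detrend_and_pad(series))
  expect_lt(abs(spec$freq_hz[which.max(spec$amplitude)] - 4), 0.35)
})

test_that("staircases converge on the psychometric function", {
  pf <- make_psychometric(10, slope_db = 4)
  # deterministic step-function observer: converge within one final step
  step_obs <- function(x) as.numeric(x > 10)
  res <- suppressWarnings(run_staircase(step_obs, start_db = 20, seed = 1))
  expect_true(all(abs(res$thresholds - 10) <= 1.5))
  # always-correct observer: no reversals, warning, NA threshold
  expect_warning(
    res1 <- run_staircase(function(x) 1,
                          staircase_config(max_trials = 60), seed = 2),
    "did not converge")
  expect_true(all(is.na(res1$thresholds)))
})

test_that("the 3-down-1-up rule holds accuracy near its 79.4% point", {
  pf <- make_psychometric(10, slope_db = 4)
  res <- suppressWarnings(
    run_staircase(pf, staircase_config(n_reversals_stop = 100000L,
                                       max_trials = 1200L),
                  start_db = 20, seed = 2))
  acc <- mean(unlist(lapply(res$tracks, function(h) h$correct[-(1:100)])))
  expect_lt(abs(acc - 0.794), 0.025)
})

test_that("the adaptive rule follows its update equations and holds the band", {
  rule <- adaptive_rule()
  hist <- rep(c(TRUE, TRUE, TRUE, FALSE), 10)  # 75% over any window
  expect_equal(adapt_difficulty(hist, 10, rule), 10)
  hist_hi <- rep(c(rep(TRUE, 9), FALSE), 3)    # 90%
  expect_equal(adapt_difficulty(hist_hi, 10, rule), 9.6)
  hist_lo <- rep(c(TRUE, FALSE), 15)           # 50%
  expect_equal(adapt_difficulty(hist_lo, 10, rule), 10.4)
  expect_equal(adapt_difficulty(c(TRUE, FALSE), 10, rule), 10)

  pf <- make_psychometric(10, slope_db = 4)
  set.seed(8)
  param <- 20; hist <- logical(0); accs <- c()
  for (i in 1:1000) {
    correct <- runif(1) < pf(param)
    hist <- c(hist, correct)
    param <- adapt_difficulty(hist, param, rule)
    if (i > 100) accs <- c(accs, mean(utils::tail(hist, 30)))
  }
  expect_gte(mean(accs), 0.69 - 0.03)
  expect_lte(mean(accs), 0.80 + 0.03)
})

test_that("the calibration generator reproduces its linear model", {
  # zero noise, zero prior SDs: y is the deterministic model curve
  cfg <- sim_config(n_participants = 3, n_trials = 50,
                    beta_priors = list(offset = c(1, 0), slope = c(0.1, 0),
                                       uv = c(0.1, 0), sin = c(0.2, 0),
                                       cos = c(0.2, 0)),
                    noise_sd = 0, with_effect = TRUE, seed = 5)
  dat <- simulate_calibration_dataset(cfg)
  t <- dat$delay_ref_s
  expected <- 1 + 0.1 * t + 0.1 * cos(2 * pi * 0.5 * (t - 0.6)) +
    0.2 * sin(2 * pi * 4 * t) + 0.2 * cos(2 * pi * 4 * t)
  expect_equal(dat$y, expected, tolerance = 1e-12)
  # without effect the rhythmic betas are zero for every participant
  cfg0 <- sim_config(with_effect = FALSE, seed = 6, n_participants = 5,
                     n_trials = 10)
  expect_true(all(attr(simulate_calibration_dataset(cfg0),
                       "betas")[, c("sin", "cos")] == 0))
})

test_that("group-mean sine beta is recovered from effect simulations", {
  est <- vapply(1:100, function(r) {
    cfg <- sim_config(noise_sd = 2, with_effect = TRUE, seed = 1000 + r)
    dat <- simulate_calibration_dataset(cfg)
    bs <- vapply(unique(dat$participant), function(p) {
      rows <- dat$participant == p
      fit_rhythm_model(dat$y[rows], dat$delay_ref_s[rows], 4,
                       "gaussian")$beta[["sin"]]
    }, numeric(1))
    mean(bs)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.05)
})

test_that("eye traces carry the configured jitter, drift and blink structure", {
  cfg <- design_config("exp1", n_blocks = 1, trials_per_block = 20,
                       seed = 51)
  d <- generate_design(cfg)
  # zero jitter, no blinks: perfectly stable fixation, all samples valid
  tr0 <- simulate_eye_traces(d, eye_trace_params(rate_hz = 100,
                                                 jitter_sd_deg = 0,
                                                 blink_rate_hz = 0), seed = 1)
  expect_true(all(tr0$valid))
  expect_true(all(tr0$x_deg == 0 & tr0$y_deg == 0))
  em0 <- compute_eye_metrics(tr0, d, min_valid_trials = 1)
  expect_true(all(em0$metrics$fixation_stability == 0))
  # blinks mark samples invalid
  trb <- simulate_eye_traces(d, eye_trace_params(rate_hz = 100,
                                                 blink_rate_hz = 2), seed = 2)
  expect_gt(sum(!trb$valid), 0)
  expect_true(all(is.na(trb$x_deg[!trb$valid])))
})

test_that("median splits recover two jitter populations", {
  cfg <- design_config("exp1", n_blocks = 2, trials_per_block = 200,
                       seed = 61)
  d <- generate_design(cfg)
  sds <- rep(c(0.2, 0.6), each = 200)
  tr <- simulate_eye_traces(d, eye_trace_params(rate_hz = 100,
                                                jitter_sd_deg = sds,
                                                blink_rate_hz = 0), seed = 3)
  em <- compute_eye_metrics(tr, d, min_valid_trials = 1)
  sp <- median_split(em, "fixation_stability", min_per_half = 1)
  m <- merge(sp$assignment,
             data.frame(trial_id = paste(d$participant_id, d$block,
                                         d$trial_index, sep = "_"),
                        pop = rep(c("low", "high"), each = 200)))
  expect_gte(mean(m$half == m$pop), 0.95)
})
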