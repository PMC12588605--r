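test_that("bootstrap prevalence equals an explicit resampling oracle", {
  params <- observer_params(d0 = 1.5,
                            rhythm = rhythm_component("dprime", 4, 0.7))
  tab <- sim_cohort(4, params, seed = 111, n_blocks = 4,
                    trials_per_block = 190)
  bm <- compute_binned_metrics(tab, ear_sets = "both")
  sc <- rhythm_scan(bm, "binned", metric = "dprime", n_perm = 200,
                    seed = 25)
  prev <- bootstrap_prevalence(sc, threshold = 0.01, n_boot = 50, seed = 26)
  # oracle: same participant draws, group statistics rebuilt by looping
  set.seed(26)
  np <- length(sc$participants)
  ns <- dim(sc$surr)[3]
  sig_oracle <- matrix(FALSE, 50, length(sc$freqs_hz))
  for (b in 1:50) {
    idx <- sample.int(np, np, replace = TRUE)
    ga <- colMeans(sc$actual[idx, , drop = FALSE])
    for (f in seq_along(sc$freqs_hz)) {
      gs <- colMeans(sc$surr[idx, f, , drop = FALSE][, 1, ])
      p <- (1 + sum(gs >= ga[f])) / (1 + ns)
      sig_oracle[b, f] <- p <= 0.01
    }
  }
  expect_identical(prev$sig, sig_oracle)
  expect_equal(prev$prevalence, colMeans(sig_oracle))
})

test_that("prevalence saturates for identical strong participants and grows with amplitude", {
  params <- observer_params(d0 = 1.5,
                            rhythm = rhythm_component("dprime", 4, 1.2))
  one <- sim_cohort(1, params, seed = 121, n_blocks = 4,
                    trials_per_block = 190)
  # clone the same participant under different ids: every resample identical
  clones <- do.call(rbind, lapply(1:4, function(i) {
    x <- as.data.frame(one)
    x$participant_id <- sprintf("c%02d", i)
    x
  }))
  bm <- compute_binned_metrics(trial_table(clones), ear_sets = "both")
  sc <- rhythm_scan(bm, "binned", metric = "dprime", n_perm = 200,
                    seed = 27)
  prev <- bootstrap_prevalence(sc, threshold = 0.05, n_boot = 100,
                               seed = 28)
  k4 <- which.min(abs(prev$freqs_hz - 4))
  expect_equal(prev$prevalence[k4], 1)

  # monotone in the injected amplitude
  weak <- sim_cohort(4, observer_params(d0 = 1.5,
                                        rhythm = rhythm_component("dprime",
                                                                  4, 0.2)),
                     seed = 131, n_blocks = 4, trials_per_block = 190)
  strong <- sim_cohort(4, observer_params(d0 = 1.5,
                                          rhythm = rhythm_component("dprime",
                                                                    4, 1.2)),
                       seed = 131, n_blocks = 4, trials_per_block = 190)
  pw <- bootstrap_prevalence(
    rhythm_scan(compute_binned_metrics(weak, ear_sets = "both"), "binned",
                metric = "dprime", n_perm = 200, seed = 29),
    threshold = 0.01, n_boot = 100, seed = 30)
  ps <- bootstrap_prevalence(
    rhythm_scan(compute_binned_metrics(strong, ear_sets = "both"), "binned",
                metric = "dprime", n_perm = 200, seed = 29),
    threshold = 0.01, n_boot = 100, seed = 30)
  expect_gte(ps$prevalence[k4], pw$prevalence[k4])
})

test_that("prevalence averaging is an element-wise mean with strict grids", {
  mk <- function(p) structure(list(approach = "binned", metric = "dprime",
                                   ear_set = "both", freqs_hz = 1:3,
                                   prevalence = p, sig = NULL,
                                   threshold = 0.01, n_boot = 10, seed = 1),
                              class = "prevalence_result")
  avg <- average_prevalence(list(mk(c(0.4, 0.4, 0.4)), mk(c(0.4, 0.4, 0.4)),
                                 mk(c(0.4, 0.4, 0.4))))
  expect_equal(avg$prevalence, c(0.4, 0.4, 0.4))
  a <- c(0.1, 0.5, 0.9); b <- c(0.3, 0.2, 0.6)
  expect_equal(average_prevalence(list(mk(a), mk(b)))$prevalence,
               (a + b) / 2)
  expect_warning(avg2 <- average_prevalence(list(mk(a), NULL)), "excluded")
  expect_equal(avg2$prevalence, a)
  bad <- mk(a); bad$freqs_hz <- 2:4
  expect_error(average_prevalence(list(mk(a), bad)), "grids differ")
})

test_that("co-occurrence correlation behaves at its extremes and under independence", {
  f <- c(rep(TRUE, 30), rep(FALSE, 70))
  cc <- cooccurrence_correlation(f, f)
  expect_equal(cc$r, 1)
  set.seed(31)
  rs <- replicate(40, {
    cooccurrence_correlation(runif(5000) < 0.3, runif(5000) < 0.3)$r
  })
  expect_gte(mean(abs(rs) < 0.05), 0.9)
  expect_warning(cc0 <- cooccurrence_correlation(rep(TRUE, 10),
                                                 rep(c(TRUE, FALSE), 5)),
                 "constant")
  expect_false(cc0$defined)
})

test_that("eye metrics match direct computation and reject tainted epochs", {
  cfg <- design_config("exp1", n_blocks = 1, trials_per_block = 8,
                       seed = 141)
  d <- generate_design(cfg)
  tr <- simulate_eye_traces(d, eye_trace_params(rate_hz = 100,
                                                jitter_sd_deg = 0.4,
                                                blink_rate_hz = 0), seed = 32)
  em <- compute_eye_metrics(tr, d, min_valid_trials = 1)
  expect_equal(nrow(em$metrics), 8)
  # direct-computation oracle for one trial
  id <- em$metrics$trial_id[1]
  delay <- d$delay_s[paste(d$participant_id, d$block, d$trial_index,
                           sep = "_") == id]
  rows <- tr$trial_id == id & tr$t_s >= 0 & tr$t_s <= delay
  expect_equal(em$metrics$fixation_stability[em$metrics$trial_id == id],
               (sd(tr$x_deg[rows]) + sd(tr$y_deg[rows])) / 2,
               tolerance = 1e-9)
  # one invalid sample anywhere in the epoch discards the whole trial
  tr2 <- tr
  bad_id <- unique(tr2$trial_id)[2]
  k <- which(tr2$trial_id == bad_id)[5]
  tr2$valid[k] <- FALSE
  em2 <- compute_eye_metrics(tr2, d, min_valid_trials = 1)
  expect_false(bad_id %in% em2$metrics$trial_id)
  expect_equal(em2$report$n_valid, 7)
  # gaze excursions beyond +/-14 degrees also invalidate
  tr3 <- tr
  tr3$x_deg[which(tr3$trial_id == bad_id)[10]] <- 20
  em3 <- compute_eye_metrics(tr3, d, min_valid_trials = 1)
  expect_false(bad_id %in% em3$metrics$trial_id)
  # constant pupil: z-scores defined as 0 with a warning
  tr4 <- tr
  tr4$pupil <- 5
  expect_warning(em4 <- compute_eye_metrics(tr4, d, min_valid_trials = 1),
                 "constant pupil")
  expect_true(all(em4$metrics$pupil_mean_z == 0))
})

test_that("median splits partition trials with ties going low", {
  m <- data.frame(trial_id = as.character(1:10), participant_id = "p01",
                  pupil_mean_z = 1:10, fixation_stability = 1,
                  valid = TRUE, stringsAsFactors = FALSE)
  sp <- median_split(m, "pupil_mean_z", min_per_half = 1)
  expect_equal(sort(as.integer(sp$assignment$trial_id[sp$assignment$half == "low"])),
               1:5)
  expect_equal(sort(as.integer(sp$assignment$trial_id[sp$assignment$half == "high"])),
               6:10)
  expect_equal(nrow(sp$assignment), 10)
  m$pupil_mean_z <- 3
  expect_warning(sp2 <- median_split(m, "pupil_mean_z", min_per_half = 1),
                 "tie")
  expect_false(sp2$report$included)  # empty high half fails the minimum
  # per-half minimum excludes participants
  sp3 <- median_split(within(m, pupil_mean_z <- 1:10), "pupil_mean_z",
                      min_per_half = 6)
  expect_false(sp3$report$included)
  expect_null(sp3$assignment)
})

test_that("condition contrasts detect a rhythm present in only one condition", {
  base <- observer_params(d0 = 1.5)
  rhythmic <- observer_params(d0 = 1.5,
                              rhythm = rhythm_component("dprime", 4, 1.2))
  tab_a <- sim_cohort(12, base, seed = 151, n_blocks = 4,
                      trials_per_block = 190)
  tab_b <- sim_cohort(12, rhythmic, seed = 151, n_blocks = 4,
                      trials_per_block = 190)
  # identity contrast: zero differences, nothing significant
  same <- contrast_conditions(tab_a, tab_a, n_boot = 20, seed = 33)
  expect_true(all(same$table$mean_diff == 0))
  expect_true(all(same$table$p_bh == 1))
  ct <- contrast_conditions(tab_a, tab_b, n_boot = 100, seed = 34)
  k4 <- which.min(abs(ct$table$freq_hz - 4))
  expect_lt(ct$table$p_bh[k4], 0.05)
  expect_gt(ct$table$mean_diff[k4], 0)
  # BH adjustment equals the step-up oracle
  expect_equal(ct$table$p_bh, bh_stepup(ct$table$p))
})

test_that("descriptive summaries track condition differences and difficulty drift", {
  cfg <- design_config("exp4", n_blocks = 4, trials_per_block = 40,
                       seed = 161)
  tab <- do.call(rbind, lapply(1:3, function(i) {
    d <- generate_design(cfg, participant_id = sprintf("p%02d", i))
    simulate_observer(d, observer_params(d0 = 1.5), seed = 35 + i)
  }))
  tab <- trial_table(tab)
  cs <- condition_summary(tab, by = "dual_task")
  expect_equal(nrow(cs$per_participant), 6)
  expect_equal(nrow(cs$tests), 3)
  expect_true(all(is.finite(cs$tests$p)))
  # single participant: summaries only, no group test
  one <- condition_summary(tab[tab$participant_id == "p01", ],
                           by = "dual_task")
  expect_null(one$tests)
  # staircase-like decreasing stimulus parameter: negative dB change
  one_tab <- tab[tab$participant_id == "p01", ]
  one_tab$stim_param <- seq(2, 1, length.out = nrow(one_tab))
  dd <- difficulty_drift(one_tab)
  expect_lt(dd$per_participant$db_change[1], 0)
  expect_equal(dd$per_participant$db_change[1], 20 * log10(1 / 2),
               tolerance = 0.35)
})
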