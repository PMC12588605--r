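# Synthetic-data module: experiment designs, rhythmically modulated
# observers, staircase and adaptive-difficulty dynamics, the calibration
# generator, and gaze/pupil traces. Everything is seeded and reproducible.

#' Experiment design configuration
#'
#' Defaults reproduce the four paradigms: `exp1`-`exp3` run 8 blocks of 190
#' trials (380 trials per ear x condition cell), `exp4` runs 16 blocks of 130
#' trials with the dual task in half the blocks (260 trials per ear x
#' condition x task cell). Target delays are sampled uniformly between 0.3
#' and 1.5 s after background-noise onset.
#'
#' @param experiment one of `"exp1"`..`"exp4"`.
#' @param n_blocks,trials_per_block block structure; defaults per experiment.
#' @param delay_window_s target-delay window (seconds after noise onset).
#' @param dual_task_blocks fraction of blocks with the dual task (exp4 only).
#' @param seed integer seed.
#' @return a `design_config` list.
#' @export
design_config <- function(experiment = c("exp1", "exp2", "exp3", "exp4"),
                          n_blocks = NULL, trials_per_block = NULL,
                          delay_window_s = c(0.3, 1.5),
                          dual_task_blocks = 0.5, seed = 1L) {
  experiment <- match.arg(experiment)
  if (is.null(n_blocks)) n_blocks <- if (experiment == "exp4") 16L else 8L
  if (is.null(trials_per_block)) {
    trials_per_block <- if (experiment == "exp4") 130L else 190L
  }
  cfg <- list(experiment = experiment, n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              delay_window_s = delay_window_s,
              dual_task_blocks = dual_task_blocks, seed = as.integer(seed))
  n_cells <- if (experiment == "exp4") 8L else 4L
  if ((cfg$n_blocks * cfg$trials_per_block) %% n_cells != 0) {
    stop_fmt("n_blocks * trials_per_block must be divisible by %d", n_cells)
  }
  if (experiment == "exp4" &&
      (cfg$n_blocks * dual_task_blocks) %% 1 != 0) {
    stop_fmt("dual_task_blocks * n_blocks must be an integer")
  }
  class(cfg) <- "design_config"
  cfg
}

#' Generate a balanced experiment design
#'
#' Assigns ear and condition so that every ear x condition (x dual-task for
#' `exp4`) cell holds exactly the same number of trials over the session,
#' with uniformly sampled target delays. For `exp4`, half of the dual-task
#' trials carry a fixation-dot intensity change at a time drawn uniformly
#' between 0.1 s after noise onset and the target.
#'
#' @param config a [design_config()].
#' @param participant_id participant label.
#' @return a [trial_table()] with empty responses (`"none"`), ready for
#'   [simulate_observer()].
#' @export
generate_design <- function(config, participant_id = "sim01") {
  set.seed(config$seed)
  nb <- config$n_blocks
  tpb <- config$trials_per_block
  n <- nb * tpb
  dual_blocks <- rep(FALSE, nb)
  if (config$experiment == "exp4") {
    n_dual <- round(nb * config$dual_task_blocks)
    dual_blocks[seq_len(nb) %% 2 == 1][seq_len(n_dual)] <- TRUE
    if (sum(dual_blocks) < n_dual) dual_blocks[!dual_blocks][seq_len(n_dual - sum(dual_blocks))] <- TRUE
  }
  block_of <- rep(seq_len(nb), each = tpb)
  dual <- dual_blocks[block_of]
  cells <- expand.grid(ear = .ears, condition = .conditions,
                       stringsAsFactors = FALSE)
  ear <- character(n); cond <- character(n)
  for (d in unique(dual)) {
    idx <- which(dual == d)
    per_cell <- length(idx) / nrow(cells)
    lab <- sample(rep(seq_len(nrow(cells)), each = per_cell))
    ear[idx] <- cells$ear[lab]
    cond[idx] <- cells$condition[lab]
  }
  delay <- runif(n, config$delay_window_s[1], config$delay_window_s[2])
  dot_change <- rep(FALSE, n)
  dot_time <- rep(NA_real_, n)
  if (any(dual)) {
    for (b in which(dual_blocks)) {
      idx <- which(block_of == b)
      chg <- sample(idx, length(idx) %/% 2)
      dot_change[chg] <- TRUE
      dot_time[chg] <- runif(length(chg), 0.1, delay[chg])
    }
  }
  df <- data.frame(
    participant_id = participant_id, experiment = config$experiment,
    block = block_of,
    trial_index = unlist(lapply(seq_len(nb), function(b) seq_len(tpb))),
    ear = ear, condition = cond, delay_s = delay,
    response = "none", correct = NA, rt_s = NA_real_, stim_param = 1,
    dual_task = dual, dot_change = dot_change, dot_response = "none",
    dot_time_s = dot_time, stringsAsFactors = FALSE
  )
  trial_table(df, metadata = list(experiment = config$experiment,
                                  seed = config$seed,
                                  provenance = "generate_design"))
}

#' Rhythmic modulation component for a simulated observer
#'
#' @param target which quantity oscillates: `"dprime"`, `"bias"` or `"rt"`
#'   (the modulation of `"rt"` acts on the square-root scale).
#' @param freq_hz modulation frequency (1-12 Hz).
#' @param amplitude peak amplitude (d-prime units, criterion units, or
#'   sqrt-seconds).
#' @param phase_rad phase offset in radians.
#' @param ear `"L"`, `"R"` or `"both"`: which ear's trials are modulated.
#' @return a `rhythm_component` list.
#' @export
rhythm_component <- function(target = c("dprime", "bias", "rt"), freq_hz,
                             amplitude, phase_rad = 0, ear = "both") {
  target <- match.arg(target)
  stopifnot(amplitude >= 0, freq_hz >= 1, freq_hz <= 12,
            ear %in% c("L", "R", "both"))
  structure(list(target = target, freq_hz = freq_hz, amplitude = amplitude,
                 phase_rad = phase_rad, ear = ear),
            class = "rhythm_component")
}

#' Simulated-observer parameters
#'
#' An equal-variance gaussian signal-detection observer with symmetric
#' evidence placement: on `f1` trials the decision variable has mean `+d'/2`,
#' on `f2` trials `-d'/2`, and the observer answers `opt1` when it exceeds
#' the criterion `c`. Sensitivity, criterion and reaction time may each carry
#' additive sinusoidal modulations of the window-relative delay. Reaction
#' times are generated on the square-root scale (base + linear drift +
#' rhythm + gaussian noise) and squared, so the analysis-side square-root
#' transform recovers approximately gaussian residuals.
#'
#' @param d0 baseline sensitivity (d-prime units).
#' @param c0 baseline criterion.
#' @param rt0 baseline sqrt reaction time (sqrt-seconds).
#' @param rt_slope linear drift of sqrt RT per second of delay.
#' @param rhythm list of [rhythm_component()]s.
#' @param lapse_rate probability of a uniform guess, in `[0, 0.1]`.
#' @param rt_noise_sd gaussian noise SD on the sqrt-RT scale.
#' @return an `observer_params` list.
#' @export
observer_params <- function(d0 = 1.5, c0 = 0, rt0 = 0.75, rt_slope = 0,
                            rhythm = list(), lapse_rate = 0,
                            rt_noise_sd = 0.05) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.1, rt_noise_sd >= 0)
  if (inherits(rhythm, "rhythm_component")) rhythm <- list(rhythm)
  structure(list(d0 = d0, c0 = c0, rt0 = rt0, rt_slope = rt_slope,
                 rhythm = rhythm, lapse_rate = lapse_rate,
                 rt_noise_sd = rt_noise_sd), class = "observer_params")
}

.rhythm_sum <- function(params, target, t, ear) {
  out <- numeric(length(t))
  for (rc in params$rhythm) {
    if (rc$target != target) next
    gate <- if (rc$ear == "both") 1 else as.numeric(ear == rc$ear)
    out <- out + gate * rc$amplitude *
      sin(2 * pi * rc$freq_hz * t + rc$phase_rad)
  }
  out
}

#' Simulate observer responses on a design
#'
#' Fills in `response`, `correct`, `rt_s` (and `rt_sqrt`) of a design table
#' according to the observer model described in [observer_params()], with
#' instantaneous sensitivity and criterion evaluated at each trial's
#' window-relative delay.
#'
#' @param design a [trial_table()] from [generate_design()].
#' @param params an [observer_params()].
#' @param seed integer seed.
#' @return the completed [trial_table()].
#' @export
simulate_observer <- function(design, params, seed = 1L) {
  set.seed(seed)
  window_start <- 0.3
  t <- design$delay_ref_s %||% (design$delay_s - window_start)
  d_t <- params$d0 + .rhythm_sum(params, "dprime", t, design$ear)
  c_t <- params$c0 + .rhythm_sum(params, "bias", t, design$ear)
  mu <- ifelse(design$condition == "f1", d_t / 2, -d_t / 2)
  p_opt1 <- pnorm(mu - c_t)
  lapse <- runif(nrow(design)) < params$lapse_rate
  p_opt1[lapse] <- 0.5
  resp_opt1 <- runif(nrow(design)) < p_opt1
  design$response <- ifelse(resp_opt1, "opt1", "opt2")
  design$correct <- resp_opt1 == (design$condition == "f1")
  rt_mu <- params$rt0 + params$rt_slope * t +
    .rhythm_sum(params, "rt", t, design$ear)
  rt_sqrt <- pmax(rt_mu + rnorm(nrow(design), 0, params$rt_noise_sd), 0)
  design$rt_s <- rt_sqrt^2
  design$rt_sqrt <- rt_sqrt
  design
}

#' Staircase configuration (3-down-1-up)
#'
#' Difficulty decreases (parameter steps down) after three consecutive
#' correct responses and increases after each error; this rule converges
#' near the 79.4% correct point of the psychometric function. The step starts
#' at `initial_step_db` and is halved at each of the first reversals until it
#' reaches `step_floor_db`; the track stops after `n_reversals_stop`
#' reversals and the threshold is the mean parameter value over the last
#' `n_reversals_average` reversals.
#'
#' @param initial_step_db,step_floor_db step sizes in dB.
#' @param n_reversals_stop reversals after which a track stops.
#' @param n_reversals_average reversals averaged for the threshold.
#' @param max_trials per-track trial cap (non-convergence guard).
#' @return a `staircase_config` list.
#' @export
staircase_config <- function(initial_step_db = 4, step_floor_db = 1,
                             n_reversals_stop = 10L,
                             n_reversals_average = 5L, max_trials = 400L) {
  stopifnot(n_reversals_average <= n_reversals_stop)
  structure(list(initial_step_db = initial_step_db,
                 step_floor_db = step_floor_db,
                 n_reversals_stop = as.integer(n_reversals_stop),
                 n_reversals_average = as.integer(n_reversals_average),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' Cumulative-gaussian psychometric function
#'
#' Proportion correct as a function of the stimulus parameter (dB):
#' `p(x) = guess + (1 - guess - lapse) * pnorm((x - threshold)/slope)`.
#'
#' @param threshold_db location of the inflection point.
#' @param slope_db spread (dB); smaller is steeper.
#' @param guess lower asymptote (chance level).
#' @param lapse lapse rate shrinking the upper asymptote.
#' @return a function mapping stimulus level to P(correct).
#' @export
make_psychometric <- function(threshold_db, slope_db = 4, guess = 0.5,
                              lapse = 0) {
  force(threshold_db); force(slope_db); force(guess); force(lapse)
  function(x) guess + (1 - guess - lapse) * pnorm((x - threshold_db) / slope_db)
}

#' Run interleaved 3-down-1-up staircases
#'
#' Simulates one staircase per ear x condition track, interleaved
#' round-robin, against a psychometric observer.
#'
#' @param psychometric a function `stim_db -> P(correct)` (see
#'   [make_psychometric()]), or a named list of four such functions
#'   (`L.f1`, `L.f2`, `R.f1`, `R.f2`).
#' @param config a [staircase_config()].
#' @param start_db starting stimulus level.
#' @param seed integer seed.
#' @return list with `thresholds` (named numeric, one per track, `NA` when a
#'   track did not converge), `tracks` (per-track data frames of stimulus
#'   level, correctness and reversal flags) and `converged` (named logical).
#' @export
run_staircase <- function(psychometric, config = staircase_config(),
                          start_db = 20, seed = 1L) {
  set.seed(seed)
  track_names <- c("L.f1", "L.f2", "R.f1", "R.f2")
  pf <- if (is.function(psychometric)) {
    stats::setNames(rep(list(psychometric), 4), track_names)
  } else psychometric
  tracks <- lapply(track_names, function(nm) {
    list(stim = start_db, level = start_db, step = config$initial_step_db,
         n_correct = 0L, dir = 0L, reversals = numeric(0), done = FALSE,
         hist = data.frame(stim = numeric(0), correct = logical(0),
                           reversal = logical(0)))
  })
  names(tracks) <- track_names
  for (trial in seq_len(config$max_trials * 4L)) {
    active <- which(!vapply(tracks, `[[`, TRUE, "done"))
    if (length(active) == 0) break
    k <- active[((trial - 1L) %% length(active)) + 1L]
    tr <- tracks[[k]]
    correct <- runif(1) < pf[[k]](tr$level)
    move <- 0L
    if (correct) {
      tr$n_correct <- tr$n_correct + 1L
      if (tr$n_correct >= 3L) { move <- -1L; tr$n_correct <- 0L }
    } else {
      move <- 1L
      tr$n_correct <- 0L
    }
    reversal <- FALSE
    if (move != 0L) {
      if (tr$dir != 0L && move != tr$dir) {
        reversal <- TRUE
        tr$reversals <- c(tr$reversals, tr$level)
        tr$step <- max(tr$step / 2, config$step_floor_db)
      }
      tr$dir <- move
    }
    tr$hist <- rbind(tr$hist, data.frame(stim = tr$level, correct = correct,
                                         reversal = reversal))
    if (move != 0L) tr$level <- tr$level + move * tr$step
    if (length(tr$reversals) >= config$n_reversals_stop ||
        nrow(tr$hist) >= config$max_trials) {
      tr$done <- TRUE
    }
    tracks[[k]] <- tr
  }
  thresholds <- vapply(tracks, function(tr) {
    nr <- length(tr$reversals)
    if (nr < config$n_reversals_average) return(NA_real_)
    mean(tr$reversals[(nr - config$n_reversals_average + 1L):nr])
  }, numeric(1))
  converged <- vapply(tracks, function(tr) {
    length(tr$reversals) >= config$n_reversals_stop
  }, logical(1))
  if (any(!converged)) {
    warn_fmt("staircase track(s) did not converge: %s",
             paste(track_names[!converged], collapse = ", "))
  }
  list(thresholds = thresholds, converged = converged,
       tracks = lapply(tracks, `[[`, "hist"))
}

#' Adaptive-difficulty rule configuration
#'
#' During the main experiment the stimulus parameter is adjusted to keep the
#' running accuracy (over the preceding `window_trials` trials) between
#' `lower_pc` and `upper_pc`, by `step_fraction` (4%) of the current value.
#'
#' @param window_trials accuracy window length.
#' @param lower_pc,upper_pc target accuracy band.
#' @param step_fraction multiplicative adjustment.
#' @return an `adaptive_rule` list.
#' @export
adaptive_rule <- function(window_trials = 30L, lower_pc = 0.69,
                          upper_pc = 0.80, step_fraction = 0.04) {
  stopifnot(lower_pc > 0, lower_pc < upper_pc, upper_pc < 1)
  structure(list(window_trials = as.integer(window_trials),
                 lower_pc = lower_pc, upper_pc = upper_pc,
                 step_fraction = step_fraction), class = "adaptive_rule")
}

#' Apply the adaptive-difficulty update
#'
#' @param history logical vector of past correctness for the relevant track
#'   (most recent last).
#' @param current current stimulus parameter.
#' @param rule an [adaptive_rule()].
#' @return the updated stimulus parameter (unchanged while fewer than
#'   `window_trials` trials are available or accuracy is inside the band).
#' @export
adapt_difficulty <- function(history, current, rule = adaptive_rule()) {
  if (length(history) < rule$window_trials) return(current)
  acc <- mean(utils::tail(history, rule$window_trials))
  if (acc > rule$upper_pc) {
    current * (1 - rule$step_fraction)
  } else if (acc < rule$lower_pc) {
    current * (1 + rule$step_fraction)
  } else {
    current
  }
}

#' Calibration-generator configuration
#'
#' The generator used to calibrate the statistical approaches: for each of
#' `n_participants` simulated participants, per-participant betas are drawn
#' once from gaussian priors and `n_trials` continuous outcomes are generated
#' as `y = b0 + b1*t + b2*uv(t) + b3*sin(2*pi*f*t) + b4*cos(2*pi*f*t) + e`,
#' with `t` uniform on `[0, 1.2]`, `uv(t) = cos(2*pi*0.5*(t - 0.6))` and
#' `e ~ N(0, noise_sd^2)`. Default priors (mean, SD): offset (1, 0.1), slope
#' (0.1, 0.1), u/v (0.1, 0.1), sine and cosine at 4 Hz (0.2, 0.1). With
#' `with_effect = FALSE` the sine and cosine betas are zero for every
#' participant.
#'
#' @param n_participants,n_trials sample sizes (defaults 25 and 700).
#' @param beta_priors named list of `c(mean, sd)` for `offset`, `slope`,
#'   `uv`, `sin`, `cos`.
#' @param rhythm_freq_hz frequency of the injected rhythm (Hz).
#' @param noise_sd additive gaussian noise SD (the calibration's SNR dial: 2-8
#'   with an effect, 2/4/6 without).
#' @param with_effect include the rhythmic betas?
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 25L, n_trials = 700L,
                       beta_priors = list(offset = c(1, 0.1),
                                          slope = c(0.1, 0.1),
                                          uv = c(0.1, 0.1),
                                          sin = c(0.2, 0.1),
                                          cos = c(0.2, 0.1)),
                       rhythm_freq_hz = 4, noise_sd = 2,
                       with_effect = TRUE, seed = 1L) {
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), beta_priors = beta_priors,
                 rhythm_freq_hz = rhythm_freq_hz, noise_sd = noise_sd,
                 with_effect = with_effect, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one calibration dataset (virtual experiment)
#'
#' @param config a [sim_config()].
#' @return data frame with `participant`, `delay_ref_s`, `y`; attribute
#'   `betas` holds the per-participant generating betas (n_participants x 5).
#' @export
simulate_calibration_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  np <- config$n_participants
  nt <- config$n_trials
  pr <- config$beta_priors
  betas <- cbind(
    offset = rnorm(np, pr$offset[1], pr$offset[2]),
    slope = rnorm(np, pr$slope[1], pr$slope[2]),
    uv = rnorm(np, pr$uv[1], pr$uv[2]),
    sin = rnorm(np, pr$sin[1], pr$sin[2]),
    cos = rnorm(np, pr$cos[1], pr$cos[2])
  )
  if (!config$with_effect) betas[, c("sin", "cos")] <- 0
  t <- runif(np * nt, 0, 1.2)
  pid <- rep(seq_len(np), each = nt)
  f <- config$rhythm_freq_hz
  y <- betas[pid, "offset"] + betas[pid, "slope"] * t +
    betas[pid, "uv"] * cos(2 * pi * 0.5 * (t - 0.6)) +
    betas[pid, "sin"] * sin(2 * pi * f * t) +
    betas[pid, "cos"] * cos(2 * pi * f * t)
  if (config$noise_sd > 0) y <- y + rnorm(np * nt, 0, config$noise_sd)
  structure(data.frame(participant = pid, delay_ref_s = t, y = y),
            betas = betas)
}

#' Eye-trace generator parameters
#'
#' @param rate_hz sampling rate (Hz).
#' @param epoch_s epoch relative to background-noise onset (seconds).
#' @param jitter_sd_deg fixation-jitter SD in degrees: a scalar (all trials),
#'   or a per-trial vector.
#' @param jitter_sd_cv when `jitter_sd_deg` is scalar, per-trial SDs are
#'   drawn lognormally around it with this coefficient of variation.
#' @param drift_deg_s linear gaze-drift rate (deg/s).
#' @param pupil_sd amplitude of the slow pupil fluctuation (arbitrary units).
#' @param blink_rate_hz expected blinks per second.
#' @param blink_dur_s blink-duration range (seconds).
#' @return an `eye_trace_params` list.
#' @export
eye_trace_params <- function(rate_hz = 500, epoch_s = c(-0.4, 1.5),
                             jitter_sd_deg = 0.3, jitter_sd_cv = 0,
                             drift_deg_s = 0, pupil_sd = 1,
                             blink_rate_hz = 0.1, blink_dur_s = c(0.1, 0.3)) {
  structure(list(rate_hz = rate_hz, epoch_s = epoch_s,
                 jitter_sd_deg = jitter_sd_deg, jitter_sd_cv = jitter_sd_cv,
                 drift_deg_s = drift_deg_s, pupil_sd = pupil_sd,
                 blink_rate_hz = blink_rate_hz, blink_dur_s = blink_dur_s),
            class = "eye_trace_params")
}

#' Simulate trial-aligned gaze and pupil traces
#'
#' Gaze is fixation jitter (gaussian, per-trial SD) plus optional linear
#' drift; pupil is a slow AR(1) fluctuation plus a per-trial offset; blinks
#' are inserted as invalid segments (`valid = FALSE`, samples `NA`) at a
#' Poisson rate.
#'
#' @param design a [trial_table()] giving the trials to trace.
#' @param params an [eye_trace_params()].
#' @param seed integer seed.
#' @return data frame `trial_id`, `participant_id`, `t_s`, `x_deg`, `y_deg`,
#'   `pupil`, `valid`; one block of rows per trial.
#' @export
simulate_eye_traces <- function(design, params = eye_trace_params(),
                                seed = 1L) {
  set.seed(seed)
  tt <- seq(params$epoch_s[1], params$epoch_s[2], by = 1 / params$rate_hz)
  ns <- length(tt)
  ntr <- nrow(design)
  sds <- params$jitter_sd_deg
  if (length(sds) == 1L) {
    sds <- if (params$jitter_sd_cv > 0) {
      sds * exp(rnorm(ntr, 0, params$jitter_sd_cv) - params$jitter_sd_cv^2 / 2)
    } else rep(sds, ntr)
  }
  stopifnot(length(sds) == ntr)
  trial_id <- paste(design$participant_id, design$block, design$trial_index,
                    sep = "_")
  a <- exp(-1 / (0.5 * params$rate_hz))  # ~0.5 s pupil time constant
  out <- vector("list", ntr)
  for (i in seq_len(ntr)) {
    x <- rnorm(ns, 0, sds[i]) + params$drift_deg_s * (tt - tt[1])
    y <- rnorm(ns, 0, sds[i])
    slow <- as.numeric(stats::filter(rnorm(ns, 0, params$pupil_sd *
                                             sqrt(1 - a^2)),
                                     a, method = "recursive",
                                     init = rnorm(1, 0, params$pupil_sd)))
    pupil <- rnorm(1, 0, params$pupil_sd) + slow
    valid <- rep(TRUE, ns)
    n_blinks <- stats::rpois(1, params$blink_rate_hz * diff(params$epoch_s))
    for (b in seq_len(n_blinks)) {
      t0 <- runif(1, params$epoch_s[1], params$epoch_s[2])
      dur <- runif(1, params$blink_dur_s[1], params$blink_dur_s[2])
      bad <- tt >= t0 & tt <= t0 + dur
      valid[bad] <- FALSE
      x[bad] <- NA; y[bad] <- NA; pupil[bad] <- NA
    }
    out[[i]] <- data.frame(trial_id = trial_id[i],
                           participant_id = design$participant_id[i],
                           t_s = tt, x_deg = x, y_deg = y, pupil = pupil,
                           valid = valid, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
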