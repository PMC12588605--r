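# Bootstrap prevalence of significant effects across participant resamples,
# ear-band co-occurrence, eye-trace metrics, median splits and paired
# condition contrasts.

#' Bootstrap prevalence of significant effects
#'
#' Draws participant samples with replacement (sample size = pool size) from
#' a completed scan, recomputes the group statistic and the group surrogate
#' distribution from the drawn participants' precomputed statistics, and
#' re-evaluates significance at each frequency against the calibrated
#' threshold. Prevalence at a frequency is the fraction of bootstrap samples
#' in which it is significant — a measure of how reproducible an effect is
#' across variations of the participant sample. No model is refit inside the
#' bootstrap: under participant exchangeability, resampling rows of the
#' precomputed actual/surrogate statistics is equivalent.
#'
#' @param scan a `rhythm_scan` object ([rhythm_scan()], [spectra_test()]).
#' @param threshold calibrated first-level p threshold ([select_threshold()]).
#' @param n_boot bootstrap samples (full scale: 5000).
#' @param seed integer seed.
#' @return a `prevalence_result`: `freqs_hz`, `prevalence` (per frequency),
#'   `sig` (n_boot x n_freq logical matrix of per-sample significance),
#'   `threshold`, `n_boot`, `seed`, plus the scan's labels.
#' @export
bootstrap_prevalence <- function(scan, threshold, n_boot = 5000L, seed = 1L) {
  if (!inherits(scan, "rhythm_scan")) stop_fmt("scan must be a rhythm_scan")
  if (is.null(scan$surr)) stop_fmt("scan lacks per-participant surrogate statistics")
  set.seed(seed)
  np <- length(scan$participants)
  nf <- length(scan$freqs_hz)
  ns <- dim(scan$surr)[3]
  A <- matrix(scan$surr, np, nf * ns)  # participants x (freq, surrogate)
  sig <- matrix(FALSE, n_boot, nf)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(np, np, replace = TRUE), np)
    ga <- drop(w %*% scan$actual) / np
    gs <- matrix(drop(w %*% A) / np, nf, ns)
    p <- (1 + rowSums(gs >= ga)) / (1 + ns)
    sig[b, ] <- p <= threshold
  }
  structure(list(approach = scan$approach, metric = scan$metric,
                 ear_set = scan$ear_set, freqs_hz = scan$freqs_hz,
                 prevalence = colMeans(sig), sig = sig,
                 threshold = threshold, n_boot = n_boot, seed = seed),
            class = "prevalence_result")
}

#' Average prevalence curves across experiments
#'
#' Unweighted per-frequency mean of prevalence curves from different
#' experiments. Entries that are `NULL` (e.g. a metric unavailable in one
#' experiment) are excluded with a warning, never silently averaged.
#'
#' @param results list of `prevalence_result` objects on identical grids.
#' @return a `prevalence_result` with the averaged curve (no `sig` matrix).
#' @export
average_prevalence <- function(results) {
  keep <- !vapply(results, is.null, logical(1))
  if (any(!keep)) {
    warn_fmt("%d missing result(s) excluded from the prevalence average",
             sum(!keep))
  }
  results <- results[keep]
  if (length(results) == 0) stop_fmt("no prevalence results to average")
  f0 <- results[[1]]$freqs_hz
  for (r in results) {
    if (length(r$freqs_hz) != length(f0) || any(abs(r$freqs_hz - f0) > 1e-9)) {
      stop_fmt("prevalence grids differ; cannot average")
    }
  }
  prev <- rowMeans(vapply(results, `[[`, numeric(length(f0)), "prevalence"))
  structure(list(approach = results[[1]]$approach,
                 metric = results[[1]]$metric, ear_set = "average",
                 freqs_hz = f0, prevalence = prev, sig = NULL,
                 threshold = results[[1]]$threshold,
                 n_boot = results[[1]]$n_boot, seed = NA_integer_),
            class = "prevalence_result")
}

#' Per-sample presence of a significant effect within a frequency band
#'
#' @param prev a `prevalence_result` with its `sig` matrix.
#' @param band_hz `c(lo, hi)` frequency band (inclusive).
#' @return logical vector, one flag per bootstrap sample.
#' @export
band_flags <- function(prev, band_hz) {
  sel <- prev$freqs_hz >= band_hz[1] - 1e-9 & prev$freqs_hz <= band_hz[2] + 1e-9
  if (!any(sel)) stop_fmt("no grid frequency inside [%g, %g] Hz",
                          band_hz[1], band_hz[2])
  apply(prev$sig[, sel, drop = FALSE], 1, any)
}

#' Correlation of effect co-occurrence between two bands
#'
#' Pearson correlation, over paired bootstrap samples, of two binary flags
#' marking the presence of a significant effect in each band (e.g. right ear
#' 1.5-2 Hz vs left ear 5.5-6 Hz). The two-sided p-value uses the
#' t-approximation with `n - 2` degrees of freedom; the flags come from the
#' same bootstrap draws, so the p-value is descriptive rather than an
#' independent-samples test.
#'
#' @param flags_a,flags_b logical vectors from [band_flags()] computed on the
#'   same bootstrap samples.
#' @return list `r`, `p`, `n`, `defined` (`FALSE` when either flag vector is
#'   constant, in which case `r` and `p` are `NA`).
#' @export
cooccurrence_correlation <- function(flags_a, flags_b) {
  stopifnot(length(flags_a) == length(flags_b))
  n <- length(flags_a)
  if (var(as.numeric(flags_a)) == 0 || var(as.numeric(flags_b)) == 0) {
    warn_fmt("a flag vector is constant; co-occurrence correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  r <- cor(as.numeric(flags_a), as.numeric(flags_b))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n, defined = TRUE)
}

#' Trial-wise eye metrics from gaze/pupil traces
#'
#' Epochs traces in a window around background-noise onset, rejects any
#' epoch containing an invalid sample (blink, missing, or gaze beyond
#' `gaze_limit_deg` on either axis), z-scores pupil size within participant
#' over all retained epochs, and computes per retained trial the mean
#' z-scored pupil and the fixation stability — the arithmetic mean of the
#' standard deviations of horizontal and vertical gaze — over the interval
#' from noise onset to the target.
#'
#' @param traces data frame from [simulate_eye_traces()] or equivalent CSV:
#'   `trial_id`, `participant_id`, `t_s`, `x_deg`, `y_deg`, `pupil`,
#'   `valid`.
#' @param table the corresponding [trial_table()] (for target delays).
#' @param epoch_s validity window around noise onset (seconds).
#' @param gaze_limit_deg gaze bound marking noisy samples (degrees).
#' @param min_valid_trials participant-inclusion threshold.
#' @return an `eye_metrics` list: `metrics` (per-trial data frame with
#'   `pupil_mean_z`, `fixation_stability`, `valid`) and `report` (per
#'   participant: `n_valid`, `included`).
#' @export
compute_eye_metrics <- function(traces, table, epoch_s = c(-0.4, 1.5),
                                gaze_limit_deg = 14,
                                min_valid_trials = 600L) {
  tid <- paste(table$participant_id, table$block, table$trial_index,
               sep = "_")
  delay_of <- stats::setNames(table$delay_s, tid)  # target time from noise onset
  in_epoch <- traces$t_s >= epoch_s[1] - 1e-9 & traces$t_s <= epoch_s[2] + 1e-9
  tr <- traces[in_epoch, , drop = FALSE]
  ok <- tr$valid & is.finite(tr$x_deg) & is.finite(tr$y_deg) &
    is.finite(tr$pupil) & abs(tr$x_deg) <= gaze_limit_deg &
    abs(tr$y_deg) <= gaze_limit_deg
  bad_trials <- unique(tr$trial_id[!ok])
  tr$epoch_ok <- !(tr$trial_id %in% bad_trials)
  metrics <- list()
  report <- list()
  for (pid in unique(tr$participant_id)) {
    prows <- tr$participant_id == pid
    good <- prows & tr$epoch_ok
    pup <- tr$pupil[good]
    mu <- mean(pup); s <- sd(pup)
    if (!is.finite(s) || s == 0) {
      warn_fmt("participant %s: constant pupil; z-scores set to 0", pid)
    }
    ids <- unique(tr$trial_id[good])
    for (id in ids) {
      rows <- good & tr$trial_id == id
      sel <- rows & tr$t_s >= 0 & tr$t_s <= delay_of[[id]]
      z <- if (is.finite(s) && s > 0) (tr$pupil[sel] - mu) / s else rep(0, sum(sel))
      metrics[[length(metrics) + 1L]] <- data.frame(
        trial_id = id, participant_id = pid,
        pupil_mean_z = mean(z),
        fixation_stability = (sd(tr$x_deg[sel]) + sd(tr$y_deg[sel])) / 2,
        valid = TRUE, stringsAsFactors = FALSE)
    }
    report[[length(report) + 1L]] <- data.frame(
      participant_id = pid, n_valid = length(ids),
      included = length(ids) >= min_valid_trials, stringsAsFactors = FALSE)
  }
  structure(list(metrics = do.call(rbind, metrics),
                 report = do.call(rbind, report)),
            class = "eye_metrics")
}

#' Within-participant median split
#'
#' Splits each participant's valid trials at the participant median of the
#' chosen metric; ties at the median go to the low half. Participants with
#' fewer than `min_per_half` trials in either half are excluded and
#' reported.
#'
#' @param eye an `eye_metrics` object (or its `metrics` data frame).
#' @param metric `"pupil_mean_z"` or `"fixation_stability"`.
#' @param min_per_half per-half trial minimum for inclusion.
#' @return list: `assignment` (per-trial data frame with `half`
#'   `"low"`/`"high"`), `report` (per participant: counts, `included`).
#' @export
median_split <- function(eye, metric = c("pupil_mean_z",
                                         "fixation_stability"),
                         min_per_half = 400L) {
  metric <- match.arg(metric)
  metrics <- if (inherits(eye, "eye_metrics")) eye$metrics else eye
  assignment <- list()
  report <- list()
  for (pid in unique(metrics$participant_id)) {
    sub <- metrics[metrics$participant_id == pid, , drop = FALSE]
    x <- sub[[metric]]
    med <- stats::median(x)
    half <- ifelse(x <= med, "low", "high")
    n_low <- sum(half == "low"); n_high <- sum(half == "high")
    if (n_high == 0) warn_fmt("participant %s: all values tie at the median; all trials in the low half", pid)
    included <- min(n_low, n_high) >= min_per_half
    if (included) {
      assignment[[length(assignment) + 1L]] <- data.frame(
        trial_id = sub$trial_id, participant_id = pid, half = half,
        stringsAsFactors = FALSE)
    }
    report[[length(report) + 1L]] <- data.frame(
      participant_id = pid, n_low = n_low, n_high = n_high,
      included = included, stringsAsFactors = FALSE)
  }
  list(assignment = if (length(assignment)) do.call(rbind, assignment) else NULL,
       report = do.call(rbind, report))
}

# Per-participant vector-strength curves from the binned approach (no
# permutations): participants x frequencies matrix.
.vs_curves <- function(table, metric, ear_set, grid) {
  binned <- compute_binned_metrics(table, ear_sets = ear_set)
  bgrid <- attr(binned, "grid")
  pids <- unique(binned$participant_id)
  out <- matrix(NA_real_, length(pids), length(grid),
                dimnames = list(pids, NULL))
  for (pid in pids) {
    series <- binned[[metric]][binned$participant_id == pid]
    keep <- is.finite(series)
    vs <- .vs_scan_gaussian(cbind(series[keep]), bgrid$centers_s[keep], grid)
    out[pid, ] <- vs[, 1]
  }
  out
}

.paired_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- apply(D, 2, sd)
  tstat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), n - 1)
  p[s == 0 & m == 0] <- 1
  p[s == 0 & m != 0] <- 0
  list(mean_diff = m, t = tstat, p = p)
}

#' Contrast rhythmicity signatures between two paired conditions
#'
#' For each participant and condition, derives the binned-approach vector
#' strength of the rhythmic predictor at each grid frequency, then contrasts
#' conditions with per-frequency paired t-tests, Benjamini-Hochberg
#' corrected across the grid. A participant bootstrap repeats the t-tests on
#' resampled cohorts and reports the prevalence of (BH-) significant
#' differences per frequency. Used for dual-task vs single-task blocks and
#' for median-split halves of pupil size or fixation stability.
#'
#' @param table_a,table_b filtered, delay-referenced [trial_table()]s for
#'   the two conditions; participants are paired by id and those missing
#'   from one condition are dropped with a warning.
#' @param metric binned metric to contrast (`"dprime"`, `"bias"`,
#'   `"mean_sqrt_rt"`).
#' @param ear_set `"L"`, `"R"` or `"both"`.
#' @param grid frequency grid (defaults to the binned grid).
#' @param alpha significance level applied to the BH-adjusted p-values.
#' @param n_boot bootstrap samples for the prevalence of differences.
#' @param seed integer seed.
#' @param condition_pair labels for the two conditions.
#' @return a `contrast_result`: `table` (per frequency: `mean_diff` (B-A),
#'   `t`, `p`, `p_bh`, `prevalence`), `vs_a`, `vs_b` (participant curves),
#'   `participants`, `alpha`, `n_boot`.
#' @export
contrast_conditions <- function(table_a, table_b, metric = "dprime",
                                ear_set = "both", grid = NULL, alpha = 0.05,
                                n_boot = 1000L, seed = 1L,
                                condition_pair = c("A", "B")) {
  if (is.null(grid)) grid <- frequency_grid("binned")
  vs_a <- .vs_curves(table_a, metric, ear_set, grid)
  vs_b <- .vs_curves(table_b, metric, ear_set, grid)
  common <- intersect(rownames(vs_a), rownames(vs_b))
  dropped <- setdiff(union(rownames(vs_a), rownames(vs_b)), common)
  if (length(dropped) > 0) {
    warn_fmt("participant(s) missing one condition dropped: %s",
             paste(dropped, collapse = ", "))
  }
  if (length(common) < 2) stop_fmt("need at least 2 paired participants")
  D <- vs_b[common, , drop = FALSE] - vs_a[common, , drop = FALSE]
  tt <- .paired_t(D)
  p_bh <- p.adjust(tt$p, method = "BH")
  set.seed(seed)
  np <- length(common)
  sig_count <- numeric(length(grid))
  for (b in seq_len(n_boot)) {
    Db <- D[sample.int(np, np, replace = TRUE), , drop = FALSE]
    ttb <- .paired_t(Db)
    sig_count <- sig_count + (p.adjust(ttb$p, method = "BH") <= alpha)
  }
  structure(list(condition_pair = condition_pair, metric = metric,
                 ear_set = ear_set,
                 table = data.frame(freq_hz = grid, mean_diff = tt$mean_diff,
                                    t = tt$t, p = tt$p, p_bh = p_bh,
                                    prevalence = sig_count / n_boot),
                 vs_a = vs_a[common, , drop = FALSE],
                 vs_b = vs_b[common, , drop = FALSE], participants = common,
                 alpha = alpha, n_boot = n_boot, seed = seed),
            class = "contrast_result")
}

#' Descriptive behavioural summary by condition
#'
#' Overall d-prime, criterion and mean reaction time per participant and
#' level of a grouping flag (e.g. dual task vs not), with group mean, s.e.m.
#' and paired t-tests between the two levels.
#'
#' @param table a filtered [trial_table()].
#' @param by name of a logical column splitting the trials (default
#'   `"dual_task"`).
#' @return list: `per_participant` (data frame), `summary` (mean and s.e.m.
#'   per level and measure), `tests` (paired t-test per measure).
#' @export
condition_summary <- function(table, by = "dual_task") {
  lv <- sort(unique(table[[by]]))
  rows <- list()
  for (pid in unique(table$participant_id)) {
    for (l in lv) {
      sub <- table[table$participant_id == pid & table[[by]] == l, ,
                   drop = FALSE]
      sdt <- compute_sdt(sum(sub$condition == "f1" & sub$response == "opt1"),
                         sum(sub$condition == "f1"),
                         sum(sub$condition == "f2" & sub$response == "opt1"),
                         sum(sub$condition == "f2"))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, level = l, dprime = sdt$dprime,
        bias = sdt$bias, mean_rt_s = mean(sub$rt_s, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  pp <- do.call(rbind, rows)
  measures <- c("dprime", "bias", "mean_rt_s")
  summ <- do.call(rbind, lapply(lv, function(l) {
    sub <- pp[pp$level == l, , drop = FALSE]
    data.frame(level = l, measure = measures,
               mean = vapply(measures, function(m) mean(sub[[m]]), 0),
               sem = vapply(measures, function(m) sd(sub[[m]]) / sqrt(nrow(sub)), 0))
  }))
  tests <- NULL
  pids <- unique(pp$participant_id)
  if (length(lv) == 2 && length(pids) >= 2) {
    tests <- do.call(rbind, lapply(measures, function(m) {
      pa <- pp[pp$level == lv[1], ]
      pb <- pp[pp$level == lv[2], ]
      a <- pa[[m]][match(pids, pa$participant_id)]
      b <- pb[[m]][match(pids, pb$participant_id)]
      tt <- t.test(b, a, paired = TRUE)
      data.frame(measure = m, mean_diff = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }
  list(per_participant = pp, summary = summ, tests = tests)
}

#' Drift of the adaptive stimulus parameter over the experiment
#'
#' Converts the stimulus parameter (proportional to voltage) to decibels
#' (`20*log10`), computes per participant the final-minus-initial difference
#' averaged over ear x condition tracks, and tests it against zero.
#'
#' @param table a [trial_table()] ordered by block and trial.
#' @return list: `per_participant` (mean dB change), `test` (one-sample
#'   t-test of the changes).
#' @export
difficulty_drift <- function(table) {
  rows <- list()
  for (pid in unique(table$participant_id)) {
    diffs <- c()
    for (e in unique(table$ear)) {
      for (cond in unique(table$condition)) {
        sub <- table[table$participant_id == pid & table$ear == e &
                       table$condition == cond, , drop = FALSE]
        if (nrow(sub) < 2) next
        sub <- sub[order(sub$block, sub$trial_index), , drop = FALSE]
        diffs <- c(diffs, 20 * log10(sub$stim_param[nrow(sub)] /
                                       sub$stim_param[1]))
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(participant_id = pid,
                                            db_change = mean(diffs),
                                            stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, rows)
  test <- if (nrow(pp) >= 2 && sd(pp$db_change) > 0) {
    tt <- t.test(pp$db_change)
    data.frame(mean_db_change = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  } else NULL
  list(per_participant = pp, test = test)
}
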