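# "Binned" and "Trials" approaches: linear models with offset, linear, u/v
# and sine/cosine predictors; vector strength of the rhythmic component;
# within-participant permutation nulls; group percentile p-values.

#' Frequency grids for the model-based approaches
#'
#' The binned approach tests 1.2-4 Hz in steps of 0.1 Hz and 4.2-8 Hz in
#' steps of 0.2 Hz (49 frequencies). The single-trial approach extends this
#' with 8.8-12 Hz in steps of 0.8 Hz (54 frequencies), exploiting the higher
#' effective temporal resolution of unbinned delays.
#'
#' @param approach `"binned"` or `"trials"`.
#' @return numeric vector of frequencies (Hz).
#' @export
frequency_grid <- function(approach = c("binned", "trials")) {
  approach <- match.arg(approach)
  g <- round(c(seq(1.2, 4, by = 0.1), seq(4.2, 8, by = 0.2)), 10)
  if (approach == "trials") g <- c(g, round(seq(8.8, 12, by = 0.8), 10))
  g
}

#' Rhythmic-model design matrix
#'
#' Five unstandardised columns evaluated at the given times: an intercept, a
#' linear delay term, a u/v-shaped term `cos(2*pi*uv_freq*(t - uv_center))`
#' (a half cycle at 0.5 Hz, symmetric about the window midpoint, capturing a
#' slow rise-and-fall across the 1.2 s window), and the sine and cosine of
#' the tested frequency.
#'
#' @param times_s evaluation times (window-relative delays, seconds).
#' @param freq_hz tested rhythm frequency (Hz).
#' @param uv_freq_hz,uv_center_s u/v term frequency and centre of symmetry.
#' @return numeric matrix with columns `offset`, `linear`, `uv`, `sin`,
#'   `cos`.
#' @export
build_design <- function(times_s, freq_hz, uv_freq_hz = 0.5,
                         uv_center_s = 0.6) {
  w <- 2 * pi * freq_hz * times_s
  cbind(offset = rep(1, length(times_s)), linear = times_s,
        uv = cos(2 * pi * uv_freq_hz * (times_s - uv_center_s)),
        sin = sin(w), cos = cos(w))
}

# Ridge-stabilised IRLS for binomial fits that fail to converge (e.g. under
# separation during permutation refits, which must never abort a null).
.ridge_logit <- function(X, y, lambda = 1e-3, maxit = 50L) {
  b <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  b
}

#' Fit the rhythmic linear model at one frequency
#'
#' Gaussian-identity fits (binned metrics, sqrt reaction times) use least
#' squares; binomial-logit fits (single-trial accuracy) use iteratively
#' reweighted least squares with a small ridge-penalised fallback when the
#' fit does not converge (e.g. separation). The vector strength of the
#' rhythmic predictor is the arithmetic mean of the squared sine and cosine
#' betas, `(beta_sin^2 + beta_cos^2)/2` — an amplitude-squared measure that
#' is independent of the phase of the underlying modulation.
#'
#' @param outcome numeric (gaussian) or 0/1 (binomial) outcome vector.
#' @param times_s window-relative delays (seconds), same length.
#' @param freq_hz tested frequency (Hz).
#' @param family `"gaussian"` or `"binomial"`.
#' @return a `rhythm_fit` list: `beta` (named length-5), `vector_strength`,
#'   `freq_hz`, `family`, `converged`.
#' @export
fit_rhythm_model <- function(outcome, times_s,
                             freq_hz, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  keep <- is.finite(outcome) & is.finite(times_s)
  outcome <- outcome[keep]; times_s <- times_s[keep]
  X <- build_design(times_s, freq_hz)
  if (family == "gaussian") {
    fit <- lm.fit(X, outcome)
    beta <- fit$coefficients
    converged <- !anyNA(beta)
    if (!converged) beta[is.na(beta)] <- 0
  } else {
    fit <- suppressWarnings(glm.fit(X, outcome, family = binomial()))
    converged <- fit$converged && fit$boundary == FALSE &&
      !anyNA(fit$coefficients)
    beta <- if (converged) fit$coefficients else {
      warn_fmt("binomial fit did not converge at %.2f Hz; ridge fallback",
               freq_hz)
      .ridge_logit(X, outcome)
    }
  }
  names(beta) <- colnames(X)
  structure(list(beta = beta,
                 vector_strength = (beta[["sin"]]^2 + beta[["cos"]]^2) / 2,
                 freq_hz = freq_hz, family = family, converged = converged),
            class = "rhythm_fit")
}

# Vector strengths for the actual outcome and all permutations, gaussian
# family, across the full grid. Ymat holds the actual outcome in column 1
# and permuted outcomes after; returns an n_freq x ncol(Ymat) matrix. The
# delay->design mapping is fixed, so permuting outcomes against delays is
# the permutation null.
#
# By Frisch-Waugh, the sine/cosine betas of the full five-column fit equal
# the betas of the residualised outcome regressed on the residualised
# sine/cosine pair (nuisance columns projected out). The nuisance block is
# identical across frequencies, so it is projected out once and each
# frequency collapses to a closed-form 2x2 system, vectorised over
# frequencies and permutations.
.vs_scan_gaussian <- function(Ymat, times, freqs) {
  if (!is.matrix(Ymat)) Ymat <- cbind(Ymat)
  Xb <- cbind(1, times, cos(2 * pi * 0.5 * (times - 0.6)))
  W <- outer(times, 2 * pi * freqs)
  SC <- cbind(sin(W), cos(W))
  XbXb <- crossprod(Xb)
  Yr <- Ymat - Xb %*% solve(XbXb, crossprod(Xb, Ymat))
  SCr <- SC - Xb %*% solve(XbXb, crossprod(Xb, SC))
  nf <- length(freqs)
  Sr <- SCr[, seq_len(nf), drop = FALSE]
  Cr <- SCr[, nf + seq_len(nf), drop = FALSE]
  a <- colSums(Sr * Sr)                 # S'S per frequency
  b <- colSums(Sr * Cr)                 # S'C
  cc <- colSums(Cr * Cr)                # C'C
  TT <- crossprod(SCr, Yr)              # 2*nf x m (dominant cost)
  U <- TT[seq_len(nf), , drop = FALSE]  # S'Y
  V <- TT[nf + seq_len(nf), , drop = FALSE]
  det <- a * cc - b^2
  det[det <= .Machine$double.eps * a * cc] <- NA_real_
  bs <- (cc * U - b * V) / det
  bc <- (a * V - b * U) / det
  (bs^2 + bc^2) / 2
}

.vs_scan_binomial <- function(Ymat, times, freqs) {
  vs <- matrix(NA_real_, length(freqs), ncol(Ymat))
  for (j in seq_along(freqs)) {
    X <- build_design(times, freqs[j])
    for (k in seq_len(ncol(Ymat))) {
      fit <- suppressWarnings(glm.fit(X, Ymat[, k], family = binomial()))
      b <- if (fit$converged && !anyNA(fit$coefficients)) {
        fit$coefficients
      } else .ridge_logit(X, Ymat[, k])
      vs[j, k] <- (b[4]^2 + b[5]^2) / 2
    }
  }
  vs
}

# Build the outcome matrix [actual, permutations] for one participant.
.perm_outcomes <- function(outcome, n_perm, seed) {
  set.seed(seed)
  idx <- batch_permutations(length(outcome), n_perm)
  cbind(outcome, matrix(outcome[idx], length(outcome)))
}

#' Permutation null of the vector strength at one frequency
#'
#' For each participant the assignment between delays and outcomes is
#' shuffled `n_perm` times and the model refit; the i-th group surrogate is
#' the participant mean of the i-th shuffle's vector strengths, and the
#' group p-value is the add-one percentile of the actual group mean within
#' the group surrogates.
#'
#' @param data list with one element per participant, each a list with
#'   `outcome` and `times_s`.
#' @param freq_hz tested frequency (Hz).
#' @param n_perm number of shuffles (full scale: 10000).
#' @param family `"gaussian"` or `"binomial"`.
#' @param seed master seed; per-participant streams derived from it.
#' @return list (class `null_distribution`): `freq_hz`, `actual`
#'   (per-participant vector strengths), `surr` (participants x n_perm),
#'   `group_actual`, `group_surr`, `p`.
#' @export
permutation_null <- function(data, freq_hz, n_perm = 1000L,
                             family = c("gaussian", "binomial"), seed = 1L) {
  family <- match.arg(family)
  np <- length(data)
  actual <- numeric(np)
  surr <- matrix(NA_real_, np, n_perm)
  for (i in seq_len(np)) {
    d <- data[[i]]
    keep <- is.finite(d$outcome) & is.finite(d$times_s)
    y <- d$outcome[keep]; tms <- d$times_s[keep]
    if (length(unique(tms)) < 2) stop_fmt("participant %d has <2 distinct delays", i)
    Ymat <- .perm_outcomes(y, n_perm, derive_seed(seed, i))
    vs <- if (family == "gaussian") {
      .vs_scan_gaussian(Ymat, tms, freq_hz)
    } else .vs_scan_binomial(Ymat, tms, freq_hz)
    actual[i] <- vs[1, 1]
    surr[i, ] <- vs[1, -1]
  }
  group_actual <- mean(actual)
  group_surr <- colMeans(surr)
  structure(list(freq_hz = freq_hz, actual = actual, surr = surr,
                 group_actual = group_actual, group_surr = group_surr,
                 p = perm_pvalue(group_actual, group_surr)),
            class = "null_distribution")
}

#' Scan a frequency grid with the model-based approaches
#'
#' Runs the rhythmic linear model and its permutation null at every grid
#' frequency. For `approach = "binned"` the input is a `binned_metrics`
#' table and the chosen metric's 20-bin series is modelled per participant
#' (gaussian family; shuffles permute metric values across bins; missing
#' bins are dropped listwise). For `approach = "trials"` the input is a
#' filtered, delay-referenced trial table; `metric = "accuracy"` fits a
#' binomial-logit model to single-trial correctness and `metric = "rt"` a
#' gaussian model to single-trial sqrt reaction times (shuffles permute the
#' delay-outcome assignment). Within a participant one set of shuffles is
#' shared across all frequencies, which preserves the across-frequency
#' dependence of the null that family-wise calibration relies on.
#'
#' @param x a `binned_metrics` table or a [trial_table()].
#' @param approach `"binned"` or `"trials"`.
#' @param metric `"dprime"`, `"bias"` or `"mean_sqrt_rt"` (binned);
#'   `"accuracy"` or `"rt"` (trials).
#' @param ear_set `"L"`, `"R"` or `"both"`.
#' @param grid frequency grid (defaults to [frequency_grid()] for the
#'   approach).
#' @param n_perm shuffles per participant (full scale: 10000).
#' @param seed master seed.
#' @param n_group number of group-level surrogates; when larger than
#'   `n_perm`, additional group surrogates are formed by seeded random
#'   re-pairing of per-participant surrogate statistics, refining the
#'   p-value resolution to `1/(n_group + 1)` without extra refits. Default:
#'   equal to `n_perm` (plain index-wise pairing).
#' @return a `rhythm_scan` object; `$table` holds `freq_hz`, `group_stat`
#'   (group-mean vector strength) and `p`, and the per-participant actual
#'   and surrogate statistics are kept for [bootstrap_prevalence()].
#' @export
rhythm_scan <- function(x, approach = c("binned", "trials"),
                        metric = "dprime", ear_set = "both", grid = NULL,
                        n_perm = 1000L, seed = 1L, n_group = NULL) {
  approach <- match.arg(approach)
  if (is.null(grid)) grid <- frequency_grid(approach)
  if (approach == "binned") {
    if (!inherits(x, "binned_metrics")) stop_fmt("binned approach needs a binned_metrics table")
    bgrid <- attr(x, "grid") %||% bin_grid()
    sub <- x[x$ear_set == ear_set, , drop = FALSE]
    pids <- unique(sub$participant_id)
    data <- lapply(pids, function(pid) {
      list(outcome = sub[[metric]][sub$participant_id == pid],
           times_s = bgrid$centers_s)
    })
    family <- "gaussian"
  } else {
    if (!metric %in% c("accuracy", "rt")) stop_fmt("trials metric must be 'accuracy' or 'rt'")
    if (is.null(x$delay_ref_s)) stop_fmt("table lacks delay_ref_s; run reference_delays() first")
    sel <- if (ear_set == "both") rep(TRUE, nrow(x)) else x$ear == ear_set
    sub <- x[sel, , drop = FALSE]
    if (metric == "rt" && is.null(sub$rt_sqrt)) sub <- transform_rt(sub)
    pids <- unique(sub$participant_id)
    data <- lapply(pids, function(pid) {
      rows <- sub$participant_id == pid
      y <- if (metric == "accuracy") as.numeric(sub$correct[rows]) else sub$rt_sqrt[rows]
      list(outcome = y, times_s = sub$delay_ref_s[rows])
    })
    family <- if (metric == "accuracy") "binomial" else "gaussian"
  }
  np <- length(data)
  actual <- matrix(NA_real_, np, length(grid))
  surr <- array(NA_real_, c(np, length(grid), n_perm))
  for (i in seq_len(np)) {
    d <- data[[i]]
    keep <- is.finite(d$outcome) & is.finite(d$times_s)
    y <- d$outcome[keep]; tms <- d$times_s[keep]
    Ymat <- .perm_outcomes(y, n_perm, derive_seed(seed, i))
    vs <- if (family == "gaussian") {
      .vs_scan_gaussian(Ymat, tms, grid)
    } else .vs_scan_binomial(Ymat, tms, grid)
    actual[i, ] <- vs[, 1]
    surr[i, , ] <- vs[, -1, drop = FALSE]
  }
  if (!is.null(n_group) && n_group > n_perm) {
    surr <- .expand_surr(surr, n_group, derive_seed(seed, 999983L))
  }
  gt <- .group_test(actual, surr)
  structure(list(approach = approach, metric = metric, ear_set = ear_set,
                 stat_name = "vector_strength", freqs_hz = grid,
                 participants = as.character(pids), actual = actual,
                 surr = surr, family = family, n_perm = n_perm,
                 n_group = dim(surr)[3], seed = seed,
                 table = data.frame(freq_hz = grid,
                                    group_stat = gt$group_stat, p = gt$p)),
            class = "rhythm_scan")
}
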