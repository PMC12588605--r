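# Delay binning and signal-detection metrics: d-prime, criterion and mean
# sqrt-RT per 60 ms delay bin, per ear and for both ears combined.

#' Delay-bin grid
#'
#' Twenty 60 ms bins covering window-relative delays 0 to 1.2 s, with centers
#' at 0.03, 0.09, ..., 1.17 s. Bins are half-open `[k*w, (k+1)*w)` except the
#' last, which includes the right edge so the full window is covered.
#'
#' @param bin_width_s bin width in seconds.
#' @param window_s analysis window (seconds, window-relative).
#' @return a `bin_grid` list with `n_bins` and `centers_s`.
#' @export
bin_grid <- function(bin_width_s = 0.06, window_s = c(0, 1.2)) {
  len <- diff(window_s)
  n_bins <- round(len / bin_width_s)
  if (abs(n_bins * bin_width_s - len) > 1e-9) {
    stop_fmt("window length must be an exact multiple of bin_width_s")
  }
  structure(list(bin_width_s = bin_width_s, window_s = window_s,
                 n_bins = as.integer(n_bins),
                 centers_s = window_s[1] + (seq_len(n_bins) - 0.5) * bin_width_s),
            class = "bin_grid")
}

#' Assign trials to delay bins
#'
#' @param delay_ref_s window-relative delays (seconds), or a [trial_table()]
#'   with a `delay_ref_s` column.
#' @param grid a [bin_grid()].
#' @return integer bin index per trial (1-based).
#' @export
assign_bins <- function(delay_ref_s, grid = bin_grid()) {
  if (is.data.frame(delay_ref_s)) delay_ref_s <- delay_ref_s$delay_ref_s
  eps <- 1e-9
  x <- delay_ref_s - grid$window_s[1]
  len <- diff(grid$window_s)
  if (any(x < -eps | x > len + eps, na.rm = TRUE)) {
    stop_fmt("delay_ref_s outside [%g, %g] at row(s) %s", grid$window_s[1],
             grid$window_s[2],
             paste(utils::head(which(x < -eps | x > len + eps), 5),
                   collapse = ", "))
  }
  k <- pmin(floor(pmax(x, 0) / grid$bin_width_s), grid$n_bins - 1)
  as.integer(k) + 1L
}

#' Signal-detection metrics from response counts
#'
#' Condition `f1` is treated as the signal: hits are `opt1` responses on `f1`
#' trials and false alarms `opt1` responses on `f2` trials. Rates use the
#' log-linear correction (0.5 added to each count, 1 to each denominator),
#' so d-prime and criterion stay finite for extreme rates. With `z` the
#' standard-normal quantile, `dprime = z(H) - z(FA)` and
#' `bias = -(z(H) + z(FA))/2` (positive = conservative toward `opt2`).
#'
#' @param n_hit,n_signal `opt1` count and trial count for `f1` trials.
#' @param n_fa,n_noise `opt1` count and trial count for `f2` trials.
#' @return list with `dprime` and `bias` (vectorised over counts).
#' @export
compute_sdt <- function(n_hit, n_signal, n_fa, n_noise) {
  h <- (n_hit + 0.5) / (n_signal + 1)
  fa <- (n_fa + 0.5) / (n_noise + 1)
  zh <- qnorm(h); zf <- qnorm(fa)
  list(dprime = zh - zf, bias = -(zh + zf) / 2)
}

#' Per-bin signal-detection metrics and mean sqrt-RT
#'
#' Computes d-prime, criterion and mean square-root reaction time over the
#' delay bins, separately per participant for the left ear, the right ear,
#' and both ears combined (the union of trials, not the average of per-ear
#' metrics). Bins missing a condition yield `NA` metrics with a warning.
#'
#' @param table a filtered, delay-referenced [trial_table()] with `rt_sqrt`
#'   (see [filter_outliers()], [transform_rt()], [reference_delays()]).
#' @param grid a [bin_grid()].
#' @param ear_sets subset of `c("L", "R", "both")`.
#' @return tidy data frame (class `binned_metrics`): `participant_id`,
#'   `ear_set`, `bin`, `bin_center_s`, `dprime`, `bias`, `mean_sqrt_rt`, `n`.
#' @export
compute_binned_metrics <- function(table, grid = bin_grid(),
                                   ear_sets = c("L", "R", "both")) {
  if (is.null(table$delay_ref_s)) {
    stop_fmt("table lacks delay_ref_s; run reference_delays() first")
  }
  if (is.null(table$rt_sqrt)) table <- transform_rt(table)
  bins <- assign_bins(table$delay_ref_s, grid)
  out <- list()
  for (pid in unique(table$participant_id)) {
    prows <- table$participant_id == pid
    for (es in ear_sets) {
      sel <- prows & (if (es == "both") TRUE else table$ear == es)
      nb <- grid$n_bins
      n_hit <- n_sig <- n_fa <- n_noi <- integer(nb)
      msr <- rep(NA_real_, nb)
      n_tot <- integer(nb)
      b <- bins[sel]
      cond <- table$condition[sel]
      opt1 <- table$response[sel] == "opt1"
      rtsq <- table$rt_sqrt[sel]
      for (k in seq_len(nb)) {
        ik <- b == k
        n_sig[k] <- sum(ik & cond == "f1")
        n_noi[k] <- sum(ik & cond == "f2")
        n_hit[k] <- sum(ik & cond == "f1" & opt1)
        n_fa[k] <- sum(ik & cond == "f2" & opt1)
        n_tot[k] <- sum(ik)
        if (n_tot[k] > 0) msr[k] <- mean(rtsq[ik])
      }
      sdt <- compute_sdt(n_hit, n_sig, n_fa, n_noi)
      empty <- n_sig == 0 | n_noi == 0
      if (any(empty)) {
        warn_fmt("participant %s ear_set %s: %d bin(s) missing a condition",
                 pid, es, sum(empty))
        sdt$dprime[empty] <- NA_real_
        sdt$bias[empty] <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, ear_set = es, bin = seq_len(nb),
        bin_center_s = grid$centers_s, dprime = sdt$dprime, bias = sdt$bias,
        mean_sqrt_rt = msr, n = n_tot, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  structure(res, class = c("binned_metrics", "data.frame"), grid = grid)
}
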