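# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add-one (permutation-style) p-value
#'
#' p = (1 + #\{surrogate >= actual\}) / (1 + n), so p is never 0 and attains
#' 1/(n+1) when the actual statistic exceeds every surrogate.
#'
#' @param actual scalar test statistic.
#' @param surrogates numeric vector of surrogate statistics.
#' @return p-value in (0, 1].
#' @keywords internal
#' @noRd
perm_pvalue <- function(actual, surrogates) {
  (1 + sum(surrogates >= actual)) / (1 + length(surrogates))
}

# Deterministic substream seeds below 2^31, derived from a master seed and
# an index (participant, replicate, ...) through a SplitMix64 finalizer
# (src/seed_mix.cpp), so related (master, index) pairs map to scattered,
# effectively independent seeds.
derive_seed <- function(master, index) {
  mix_seed(as.double(master), as.double(index))
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
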