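# Trial-table data model: canonical per-trial schema, CSV readers/writers,
# outlier filtering, reaction-time transform and delay re-referencing.

# Canonical column order and types. `dot_*` columns are only meaningful for
# the dual-task experiment but are always present so the schema is fixed.
.trial_columns <- c(
  participant_id = "character", experiment = "character", block = "integer",
  trial_index = "integer", ear = "character", condition = "character",
  delay_s = "numeric", response = "character", correct = "logical",
  rt_s = "numeric", stim_param = "numeric", dual_task = "logical",
  dot_change = "logical", dot_response = "character"
)

.experiments <- c("exp1", "exp2", "exp3", "exp4")
.ears <- c("L", "R")
.conditions <- c("f1", "f2")
.responses <- c("opt1", "opt2", "none")

#' Construct and validate a trial table
#'
#' A trial table holds one row per trial with a fixed schema: participant and
#' experiment identifiers, block and trial counters, the stimulated ear
#' (`L`/`R`), the stimulus condition (`f1`/`f2`; tone identity or pitch
#' order), the target delay in seconds after background-noise onset, the
#' response (`opt1`/`opt2`/`none`), its correctness, the reaction time in
#' seconds (`NA` when no response was given), the adaptive stimulus parameter,
#' and dual-task flags. Extra columns (e.g. `rt_sqrt`, `delay_ref_s`) are
#' preserved.
#'
#' @param df data frame with at least the canonical columns.
#' @param metadata named list stored as the `metadata` attribute.
#' @param validate run invariant checks (duplicate trial ids, enum levels,
#'   delay window, response/RT consistency)?
#' @return a `trial_table` (a data frame).
#' @export
trial_table <- function(df, metadata = list(), validate = TRUE) {
  missing_cols <- setdiff(names(.trial_columns), names(df))
  if (length(missing_cols) > 0) {
    stop_fmt("missing column %s", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$block <- as.integer(df$block)
  df$trial_index <- as.integer(df$trial_index)
  if (validate) .validate_trials(df)
  structure(df, class = c("trial_table", "data.frame"),
            metadata = metadata)
}

.validate_trials <- function(df) {
  bad_exp <- setdiff(unique(df$experiment), .experiments)
  if (length(bad_exp)) stop_fmt("unknown experiment label: %s", bad_exp[1])
  bad_ear <- setdiff(unique(df$ear), .ears)
  if (length(bad_ear)) stop_fmt("unknown ear label: %s", bad_ear[1])
  bad_cond <- setdiff(unique(df$condition), .conditions)
  if (length(bad_cond)) stop_fmt("unknown condition label: %s", bad_cond[1])
  key <- paste(df$participant_id, df$block, df$trial_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop_fmt("duplicate (participant_id, block, trial_index) at row %d",
             which(duplicated(key))[1])
  }
  if (any(df$rt_s < 0, na.rm = TRUE)) {
    stop_fmt("negative rt_s at row %d", which(df$rt_s < 0)[1])
  }
  none <- df$response == "none"
  if (any(none & !is.na(df$rt_s))) {
    stop_fmt("response 'none' with a reaction time at row %d",
             which(none & !is.na(df$rt_s))[1])
  }
}

#' Read a trial table from CSV
#'
#' Strict reader for the canonical schema (comma separated, UTF-8, header
#' row, `.` decimal). Column names must match exactly; a missing required
#' column is a format error naming the column.
#'
#' @param path file path.
#' @return a [trial_table()] with `metadata$path` set.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.trial_columns), names(df))
  if (length(missing_cols) > 0) {
    stop_fmt("missing column %s", paste(missing_cols, collapse = ", "))
  }
  for (col in names(.trial_columns)) {
    target <- .trial_columns[[col]]
    parsed <- switch(target,
      character = as.character(df[[col]]),
      integer = suppressWarnings(as.integer(df[[col]])),
      numeric = suppressWarnings(as.numeric(df[[col]])),
      logical = .parse_logical(df[[col]])
    )
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & df[[col]] != "NA" &
                   df[[col]] != "")
    if (length(bad) > 0 && target != "character") {
      stop_fmt("cannot parse column %s as %s at line %d", col, target,
               bad[1] + 1L)
    }
    df[[col]] <- parsed
  }
  trial_table(df, metadata = list(path = path))
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  as.logical(toupper(trimws(as.character(x))))
}

#' Write a trial table to CSV
#'
#' @param table a [trial_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' Remove outlier and off-task trials
#'
#' Retains trials whose response is one of the task keys (`opt1`/`opt2`) and
#' whose reaction time lies in `[min_rt_s, max_rt_s]`. Trials with very fast
#' (< 150 ms) or slow (> 2.5 s) responses, missed responses and presses of a
#' button not assigned to the task are all removed here, so this is the
#' single filtering entry point before any metric is computed.
#'
#' @param table a [trial_table()].
#' @param min_rt_s,max_rt_s reaction-time bounds in seconds.
#' @return the filtered table; attribute `removed` holds counts per reason
#'   (`no_response`, `off_task_key`, `rt_fast`, `rt_slow`).
#' @export
filter_outliers <- function(table, min_rt_s = 0.15, max_rt_s = 2.5) {
  resp <- table$response
  no_resp <- resp == "none" | is.na(table$rt_s)
  off_key <- !no_resp & !(resp %in% c("opt1", "opt2"))
  rt_fast <- !no_resp & !off_key & table$rt_s < min_rt_s
  rt_slow <- !no_resp & !off_key & table$rt_s > max_rt_s
  keep <- !(no_resp | off_key | rt_fast | rt_slow)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) warn_fmt("no trials retained after outlier filtering")
  attr(out, "removed") <- c(no_response = sum(no_resp),
                            off_task_key = sum(off_key),
                            rt_fast = sum(rt_fast), rt_slow = sum(rt_slow))
  attr(out, "metadata") <- attr(table, "metadata")
  class(out) <- class(table)
  out
}

#' Square-root transform of reaction times
#'
#' Adds `rt_sqrt = sqrt(rt_s)`; `rt_s` is preserved. Square-root transformed
#' reaction times are the quantity analysed throughout (binned means and
#' single-trial gaussian fits).
#'
#' @param table a [trial_table()].
#' @return the table with an `rt_sqrt` column.
#' @export
transform_rt <- function(table) {
  if (any(table$rt_s < 0, na.rm = TRUE)) {
    stop_fmt("negative rt_s at row %d", which(table$rt_s < 0)[1])
  }
  table$rt_sqrt <- sqrt(table$rt_s)
  table
}

#' Re-reference delays to the start of the target-uncertainty window
#'
#' Targets occur 0.3 to 1.5 s after background-noise onset; analyses use the
#' delay relative to the start of that window, `delay_ref_s = delay_s -
#' window_start_s`, spanning 0 to 1.2 s.
#'
#' @param table a [trial_table()].
#' @param window_start_s start of the delay window (seconds).
#' @param window_len_s length of the delay window (seconds).
#' @return the table with a `delay_ref_s` column.
#' @export
reference_delays <- function(table, window_start_s = 0.3,
                             window_len_s = 1.2) {
  eps <- 1e-9
  bad <- which(table$delay_s < window_start_s - eps |
                 table$delay_s > window_start_s + window_len_s + eps)
  if (length(bad) > 0) {
    stop_fmt("delay_s outside [%g, %g] at row(s) %s", window_start_s,
             window_start_s + window_len_s,
             paste(utils::head(bad, 5), collapse = ", "))
  }
  table$delay_ref_s <- pmin(pmax(table$delay_s - window_start_s, 0),
                            window_len_s)
  table
}
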