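trial_columns <- c("participant_id", "level_id", "fov_mode", "time_s",
                   "attempts", "success", "seed")

#' Read or write a trial log CSV
#'
#' One row per (participant, level) outcome with columns `participant_id`,
#' `level_id`, `fov_mode`, `time_s`, `attempts`, `success`, `seed`.
#' `read_trials()` validates the schema and reports malformed rows with
#' their file line numbers; a completed trial must have at least one
#' attempt (every release increments the counter, including the successful
#' one) and a non-negative time.
#'
#' @param trials Trials data frame (e.g. `simulate_cohort(...)$trials`).
#' @param path File path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (inherits(trials, "vg_cohort")) trials <- trials$trials
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss))
    vg_stop(paste("trials lack columns:", paste(miss, collapse = ", ")),
            "vg_schema_error")
  utils::write.csv(trials[trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_columns, names(df))
  if (length(miss))
    vg_stop(paste("trial file lacks columns:",
                  paste(miss, collapse = ", ")), "vg_schema_error")
  if (nrow(df) == 0L) return(df)
  df$success <- as.logical(df$success)
  bad <- !is.finite(df$time_s) | df$time_s < 0 |
    !is.finite(df$attempts) | df$attempts != as.integer(df$attempts) |
    (df$success & df$attempts < 1L) |
    !df$level_id %in% 1:7 | !df$fov_mode %in% c("full", "limited") |
    is.na(df$success)
  if (any(bad))
    vg_stop(paste("malformed trial rows at line(s):",
                  paste(which(bad) + 1L, collapse = ", ")),
            "vg_validation_error")
  df
}

#' Build an analysis report from a trial log
#'
#' Emits the study's result structure: per-level summaries (time and
#' attempts, with t-based 95% CIs) and a Welch comparison for every
#' requested level pair, plus the configuration fingerprint and the seeds
#' present in the data. Deterministic: the same inputs always serialize to
#' identical bytes.
#'
#' @param trials Trials data frame or `vg_cohort`.
#' @param pairs List of `c(reference_level, comparison_level)` pairs;
#'   default the two matched FOV pairs.
#' @param metric Metric for the pair comparisons.
#' @param config A [run_config()] recorded for provenance.
#' @return A list of class `vg_report`.
#' @export
run_report <- function(trials, pairs = list(c(4, 5), c(6, 7)),
                       metric = c("time", "attempts"),
                       config = run_config()) {
  metric <- match.arg(metric)
  if (inherits(trials, "vg_cohort")) trials <- trials$trials
  if (is.null(trials) || nrow(trials) == 0L)
    vg_stop("no trials to report on", "vg_data_error")
  levels_present <- sort(unique(trials$level_id))
  summaries <- lapply(levels_present, function(l) {
    tt <- trials[trials$level_id == l, ]
    list(level_id = l, n = nrow(tt),
         time = summarize_values(tt$time_s),
         attempts = summarize_values(tt$attempts))
  })
  comparisons <- lapply(pairs, function(pr)
    compare_levels(trials, pr[1L], pr[2L], metric = metric))
  structure(
    list(summaries = summaries, comparisons = comparisons, metric = metric,
         n_trials = nrow(trials), seeds = sort(unique(trials$seed)),
         config_fingerprint = config_fingerprint(config)),
    class = "vg_report"
  )
}

#' Serialize a report
#'
#' @param report A `vg_report`.
#' @return `report_json()` returns a JSON string; `report_text()` a
#'   character vector of human-readable lines.
#' @export
report_json <- function(report) {
  obj <- list(
    metric = report$metric,
    n_trials = report$n_trials,
    seeds = report$seeds,
    config_fingerprint = report$config_fingerprint,
    summaries = lapply(report$summaries, function(s) list(
      level_id = s$level_id, n = s$n,
      time = unclass(s$time), attempts = unclass(s$attempts))),
    comparisons = lapply(report$comparisons, unclass)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname report_json
#' @export
report_text <- function(report) {
  lines <- c(
    sprintf("Trials: %d   metric for comparisons: %s   config %s",
            report$n_trials, report$metric, report$config_fingerprint),
    "Level  Time mean (SD)  95% CI       Attempts mean (SD)  95% CI")
  for (s in report$summaries) {
    lines <- c(lines, sprintf(
      "%5d  %-14s  %-11s  %-18s  %s",
      s$level_id, format_mean_sd(s$time), format_ci(s$time),
      format_mean_sd(s$attempts), format_ci(s$attempts)))
  }
  for (cmp in report$comparisons) {
    lines <- c(lines, sprintf(
      "Level %s vs %s (%s): t=%.2f df=%.1f p=%s d=%.2f +%.1f%%",
      cmp$level_a, cmp$level_b, cmp$metric, cmp$t_stat, cmp$df,
      format_p(cmp$p_two_sided), cmp$d, cmp$pct_increase))
  }
  lines
}

#' @export
print.vg_report <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}
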