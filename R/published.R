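#' Published per-level summary statistics
#'
#' The per-level summary table reported by the original 25-participant user
#' study: mean, SD and printed 95% CI of completion time (seconds) and of
#' the number of attempts, per level. These printed numbers are inputs — the
#' raw data were never published — and anchor the simulator calibration and
#' the CI-reproduction checks.
#'
#' @return A data frame with columns `level_id`, `n`, `time_mean`,
#'   `time_sd`, `time_ci` (printed string), `attempts_mean`, `attempts_sd`,
#'   `attempts_ci`.
#' @export
#' @examples
#' study_summaries()
study_summaries <- function() {
  data.frame(
    level_id = 1:7,
    n = 25L,
    time_mean = c(5.7, 3.3, 7.2, 6.4, 12.5, 9.8, 16.4),
    time_sd   = c(3.6, 2.6, 2.8, 3.3, 5.7, 4.8, 11.0),
    time_ci   = c("4.2-6.9", "2.2-4.4", "6.0-8.4", "5.0-7.8",
                  "10.2-14.8", "7.8-11.8", "11.9-20.9"),
    attempts_mean = c(1.3, 1.2, 1.4, 1.6, 1.4, 1.8, 1.6),
    attempts_sd   = c(2.0, 0.7, 1.1, 1.1, 0.7, 0.9, 1.2),
    attempts_ci   = c("0.5-2.1", "0.9-1.5", "0.9-1.9", "1.2-2.0",
                      "1.1-1.7", "1.4-2.2", "1.1-2.1"),
    stringsAsFactors = FALSE
  )
}

#' Published post-game questionnaire yes-counts
#'
#' @return A data frame with `question`, `yes`, `n`.
#' @export
postgame_questionnaire <- function() {
  data.frame(
    question = c(
      "Did playing this game enhance your understanding of the limited field of view in laparoscopic surgery?",
      "Do you think this game is clinically relevant?",
      "Do you think the difficulty increased with each level?",
      "Did you find the game engaging?",
      "Did you find the game layout visually pleasing?"),
    yes = c(20L, 19L, 20L, 22L, 22L),
    n = 22L,
    stringsAsFactors = FALSE
  )
}
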