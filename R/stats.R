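#' Summary statistics with a t-based 95% confidence interval
#'
#' Mean, sample SD (n-1 denominator) and the t-based confidence interval
#' `mean +/- t(1-(1-conf)/2, n-1) * sd / sqrt(n)`. When formatted for
#' reporting, values are rounded to one decimal place.
#'
#' @param values Numeric vector, length >= 2.
#' @param conf Confidence level, default 0.95.
#' @return A list of class `vg_summary` with `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `conf`.
#' @export
#' @examples
#' summarize_values(c(5, 6, 7, 8))
summarize_values <- function(values, conf = 0.95) {
  values <- as.double(values)
  if (length(values) < 2L || any(!is.finite(values)))
    vg_stop("need at least 2 finite values to summarise",
            "vg_insufficient_data")
  summary_from_stats(mean(values), stats::sd(values), length(values), conf)
}

#' Summary interval from printed mean, SD and n
#'
#' Rebuilds the t-based confidence interval from already-summarised data
#' (e.g. a published table of per-level means and SDs).
#'
#' @param mean,sd,n Summary statistics; `n >= 2`, `sd >= 0`.
#' @param conf Confidence level.
#' @return A `vg_summary`, as for [summarize_values()].
#' @export
summary_from_stats <- function(mean, sd, n, conf = 0.95) {
  if (n < 2L) vg_stop("need n >= 2", "vg_insufficient_data")
  if (sd < 0) vg_stop("sd must be non-negative", "vg_insufficient_data")
  half <- stats::qt(1 - (1 - conf) / 2, n - 1L) * sd / sqrt(n)
  structure(list(n = as.integer(n), mean = mean, sd = sd,
                 ci_low = mean - half, ci_high = mean + half, conf = conf),
            class = "vg_summary")
}

#' Format a summary the way the study tables print it
#'
#' @param s A `vg_summary`.
#' @param digits Decimal places (the study prints 1).
#' @return `format_mean_sd()` gives `"6.4 (3.3)"`, `format_ci()` gives
#'   `"5.0-7.8"`.
#' @export
format_mean_sd <- function(s, digits = 1) {
  sprintf("%.*f (%.*f)", digits, s$mean, digits, s$sd)
}

#' @rdname format_mean_sd
#' @export
format_ci <- function(s, digits = 1) {
  sprintf("%.*f-%.*f", digits, s$ci_low, digits, s$ci_high)
}

#' @export
print.vg_summary <- function(x, ...) {
  cat(sprintf("n=%d  mean (SD) %s   %.0f%% CI %s\n", x$n,
              format_mean_sd(x), 100 * x$conf, format_ci(x)))
  invisible(x)
}

#' Welch two-sample t test from summary statistics
#'
#' The unequal-variance t statistic
#' `t = (m2 - m1) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p value.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t_stat`, `df`, `p_two_sided`.
#' @export
#' @examples
#' welch_test(6.4, 3.3, 25, 12.5, 5.7, 25)
welch_test <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L)
    vg_stop("both groups need n >= 2", "vg_insufficient_data")
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    vg_stop("group SDs must be non-negative and not both zero",
            "vg_degenerate_comparison")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t_stat <- (m2 - m1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t_stat = t_stat, df = df, p_two_sided = p)
}

#' Cohen's d for equal group sizes
#'
#' Absolute standardised mean difference
#' `|m2 - m1| / sqrt((s1^2 + s2^2) / 2)` — the pooled-SD form for equal
#' group sizes.
#'
#' @param m1,s1,m2,s2 Group means and SDs.
#' @return Non-negative effect size.
#' @export
cohen_d <- function(m1, s1, m2, s2) {
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    vg_stop("group SDs must be non-negative and not both zero",
            "vg_degenerate_comparison")
  abs(m2 - m1) / sqrt((s1^2 + s2^2) / 2)
}

#' Percent increase of a mean over a reference mean
#'
#' @param m_ref Reference mean, > 0.
#' @param m_new New mean.
#' @return `100 * (m_new - m_ref) / m_ref`.
#' @export
percent_increase <- function(m_ref, m_new) {
  if (!is.finite(m_ref) || m_ref <= 0)
    vg_stop("reference mean must be positive", "vg_domain_error")
  100 * (m_new - m_ref) / m_ref
}

#' Compare two levels of a trial dataset
#'
#' Assembles the per-participant values of `metric` for each level and
#' reports the Welch test, Cohen's d and the percent increase of level_b's
#' mean over level_a's. Mirrors the study's planned comparisons of the
#' matched level pairs (4 vs 5, 6 vs 7).
#'
#' @param x A `vg_cohort`, or a trials data frame (see [read_trials()]).
#' @param level_a Reference level (the full-FOV member of a matched pair).
#' @param level_b Comparison level.
#' @param metric `"time"` or `"attempts"`.
#' @return A list of class `vg_comparison`: `level_a`, `level_b`, `metric`,
#'   `n1`, `n2`, `t_stat`, `df`, `p_two_sided`, `d`, `pct_increase`.
#' @export
compare_levels <- function(x, level_a, level_b,
                           metric = c("time", "attempts")) {
  metric <- match.arg(metric)
  trials <- if (inherits(x, "vg_cohort")) x$trials else x
  col <- if (metric == "time") "time_s" else "attempts"
  va <- trials[[col]][trials$level_id == level_a]
  vb <- trials[[col]][trials$level_id == level_b]
  if (length(va) < 2L || length(vb) < 2L)
    vg_stop(sprintf("levels %s and %s both need at least 2 trials",
                    level_a, level_b), "vg_data_error")
  w <- welch_test(mean(va), stats::sd(va), length(va),
                  mean(vb), stats::sd(vb), length(vb))
  structure(
    list(level_a = level_a, level_b = level_b, metric = metric,
         n1 = length(va), n2 = length(vb),
         t_stat = w$t_stat, df = w$df, p_two_sided = w$p_two_sided,
         d = cohen_d(mean(va), stats::sd(va), mean(vb), stats::sd(vb)),
         pct_increase = percent_increase(mean(va), mean(vb))),
    class = "vg_comparison"
  )
}

#' @export
print.vg_comparison <- function(x, ...) {
  cat(sprintf(
    "Level %s vs %s (%s): t=%.2f, df=%.1f, p=%s, d=%.2f, +%.1f%%\n",
    x$level_a, x$level_b, x$metric, x$t_stat, x$df,
    format_p(x$p_two_sided), x$d, x$pct_increase))
  invisible(x)
}

#' Format a p value in journal style
#'
#' Three decimals without the leading zero, `"<.001"` below that threshold.
#'
#' @param p A probability.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (p < 0.001) return("<.001")
  sub("^0", "", sprintf("%.3f", p))
}

#' Per-group sample size for a two-sample t test
#'
#' Smallest `n` per group such that a two-sided two-sample t test at level
#' `alpha` reaches the requested power against effect size `d`, using the
#' noncentral t distribution (exact at small n, where this game's effects
#' live) rather than the normal approximation.
#'
#' @param d Cohen's d, > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_max Search cap.
#' @return Integer n per group (>= 2).
#' @export
#' @examples
#' required_n(0.79, 0.05, 0.80)
required_n <- function(d, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (!is.finite(d) || d <= 0) vg_stop("d must be > 0", "vg_domain_error")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    vg_stop("alpha and power must lie in (0, 1)", "vg_domain_error")
  for (n in 2:n_max) {
    if (t_test_power(n, d, alpha) >= power) return(as.integer(n))
  }
  vg_stop("no n below the search cap reaches the requested power",
          "vg_domain_error")
}

#' Exact power of the two-sided two-sample t test
#'
#' @param n Per-group sample size.
#' @param d Effect size.
#' @param alpha Two-sided level.
#' @return Power in (0, 1).
#' @export
t_test_power <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Questionnaire arithmetic
#'
#' With `n` supplied, `x` is a vector of yes-counts and the result is the
#' integer-rounded percentage of yes answers. Without `n`, `x` is a vector
#' or matrix of per-item scores and the result is the per-item mean rounded
#' to one decimal.
#'
#' @param x Yes-counts or item scores.
#' @param n Number of respondents (yes/no form only).
#' @return Numeric vector of percentages or item means.
#' @export
#' @examples
#' questionnaire_summary(c(20, 22), n = 22)
questionnaire_summary <- function(x, n = NULL) {
  if (!is.null(n)) {
    if (n <= 0) vg_stop("n must be positive", "vg_domain_error")
    return(round(100 * x / n))
  }
  if (is.matrix(x) || is.data.frame(x))
    return(round(colMeans(as.matrix(x)), 1))
  round(mean(x), 1)
}
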