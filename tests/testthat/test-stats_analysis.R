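test_that("summary intervals reproduce the printed level-4 time CI", {
  s <- summary_from_stats(6.4, 3.3, 25)
  expect_equal(format_ci(s), "5.0-7.8")
  expect_equal(format_mean_sd(s), "6.4 (3.3)")
  v <- values_with_stats(6.4, 3.3, 25)
  s2 <- summarize_values(v)
  expect_equal(s2$mean, 6.4)
  expect_equal(s2$sd, 3.3)
  expect_equal(format_ci(s2), "5.0-7.8")
  expect_error(summarize_values(3), class = "vg_insufficient_data")
})

test_that("a constant sample collapses the interval onto the mean", {
  s <- summarize_values(rep(4.2, 10))
  expect_equal(s$sd, 0)
  expect_equal(s$ci_low, 4.2)
  expect_equal(s$ci_high, 4.2)
})

test_that("summary CI coverage is ~95% on Normal data", {
  # 20,000 replications here; the acceptance suite runs the full 100,000
  set.seed(8)
  n <- 10; reps <- 20000
  x <- matrix(rnorm(n * reps, mean = 3, sd = 2), nrow = reps)
  m <- rowMeans(x)
  s <- sqrt((rowSums(x^2) - n * m^2) / (n - 1))
  half <- qt(0.975, n - 1) * s / sqrt(n)
  cover <- mean(m - half <= 3 & 3 <= m + half)
  expect_equal(cover, 0.95, tolerance = 0.01)
})

test_that("welch_test matches its closed form and the pooled t limit", {
  w <- welch_test(6.4, 3.3, 25, 12.5, 5.7, 25)
  expect_lt(w$p_two_sided, 0.001)
  expect_equal(w$t_stat, 4.6306, tolerance = 1e-4)

  same <- welch_test(5, 2, 20, 5, 2, 20)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_two_sided, 1)

  # frozen values for the 6 vs 7 comparison from printed summaries
  w67 <- welch_test(9.8, 4.8, 25, 16.4, 11.0, 25)
  expect_equal(w67$t_stat, 2.7497, tolerance = 1e-4)
  expect_equal(w67$df, 32.83, tolerance = 1e-3)
  expect_equal(w67$p_two_sided, 0.0096265, tolerance = 1e-4)

  # equal variances, equal n: Welch df collapses to n1+n2-2 and matches
  # the pooled Student t
  set.seed(2)
  for (i in 1:20) {
    m1 <- runif(1, 0, 10); m2 <- runif(1, 0, 10)
    s <- runif(1, 0.5, 5); n <- sample(3:50, 1)
    w <- welch_test(m1, s, n, m2, s, n)
    tp <- (m2 - m1) / (s * sqrt(2 / n))
    expect_equal(w$t_stat, tp, tolerance = 1e-9)
    expect_equal(w$df, 2 * n - 2, tolerance = 1e-9)
    expect_equal(w$p_two_sided, 2 * pt(abs(tp), 2 * n - 2, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
  expect_error(welch_test(1, 0, 10, 2, 0, 10),
               class = "vg_degenerate_comparison")
})

test_that("welch p agrees with numerical integration of the t density", {
  for (t_stat in c(0.3, 1.0, 2.2, 4.6)) {
    for (df in c(3.7, 10, 32.83, 48)) {
      p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
      expect_equal(p, oracle_t_p(t_stat, df), tolerance = 1e-6)
    }
  }
})

test_that("cohen_d is the equal-n pooled standardised difference", {
  expect_equal(cohen_d(5, 2, 5, 3), 0)
  expect_equal(cohen_d(5, 2, 8, 3), cohen_d(15, 2, 18, 3))  # shift invariant
  expect_equal(cohen_d(9.8, 4.8, 16.4, 11.0), 0.7777, tolerance = 1e-4)
  expect_equal(cohen_d(6.4, 3.3, 12.5, 5.7), 1.3098, tolerance = 1e-4)
})

test_that("percent_increase does the Table arithmetic", {
  expect_equal(percent_increase(9.8, 16.4), 67.3469, tolerance = 1e-4)
  expect_equal(percent_increase(6.4, 12.5), 95.3125, tolerance = 1e-4)
  expect_equal(percent_increase(5, 5), 0)
  expect_error(percent_increase(0, 5), class = "vg_domain_error")
})

test_that("compare_levels delegates correctly and respects the null", {
  # type-I calibration: beta_fov = 0 on matched-baseline alphas
  p0 <- player_params(beta_fov = 0,
                      alpha_level = log(c(5.7, 3.3, 7.2, 6.4, 6.4, 9.8, 9.8)))
  rej <- vapply(1:200, function(r) {
    co <- simulate_cohort(25, params = p0, seed = 3000 + r)
    compare_levels(co, 4, 5, "time")$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)

  co <- simulate_cohort(25, seed = 17)
  cmp <- compare_levels(co, 4, 5, "time")
  v4 <- co$trials$time_s[co$trials$level_id == 4]
  v5 <- co$trials$time_s[co$trials$level_id == 5]
  w <- welch_test(mean(v4), sd(v4), 25, mean(v5), sd(v5), 25)
  expect_equal(cmp$t_stat, w$t_stat)
  expect_equal(cmp$p_two_sided, w$p_two_sided)
  expect_equal(cmp$d, cohen_d(mean(v4), sd(v4), mean(v5), sd(v5)))
  expect_error(compare_levels(co$trials[co$trials$level_id != 4, ], 4, 5),
               class = "vg_data_error")
})

test_that("required_n uses the noncentral t and is monotone", {
  expect_error(required_n(-1), class = "vg_domain_error")
  # power -> 0+ gives the minimum valid group size
  expect_equal(required_n(1.0, 0.05, 1e-6), 2L)
  # monotone non-increasing in d
  ds <- c(0.3, 0.5, 0.8, 1.2, 2)
  ns <- vapply(ds, required_n, integer(1))
  expect_true(all(diff(ns) <= 0))
  # the returned n reaches the target, n-1 does not
  for (d in c(0.5, 0.8, 1.2)) {
    n <- required_n(d, 0.05, 0.80)
    expect_gte(t_test_power(n, d), 0.80)
    if (n > 2) expect_lt(t_test_power(n - 1, d), 0.80)
    # independent oracle: R's own noncentral-t power routine
    ref <- stats::power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05)
    expect_gte(ref$power, 0.80)
  }
  # simulation check at d = 0.8
  set.seed(12)
  n8 <- required_n(0.8, 0.05, 0.80)
  expect_gte(simulated_welch_power(n8, 0.8, reps = 4000), 0.78)
})

test_that("questionnaire arithmetic matches the printed tables", {
  q <- postgame_questionnaire()
  expect_equal(questionnaire_summary(q$yes, n = 22), c(91, 86, 91, 100, 100))
  expect_equal(questionnaire_summary(0, n = 10), 0)
  scores <- cbind(mental = c(4, 5, 5.7), physical = c(1, 2, 1.8))
  expect_equal(questionnaire_summary(scores),
               c(mental = 4.9, physical = 1.6))
})

test_that("formatting reproduces the printed CI strings", {
  tab <- study_summaries()
  # times: levels 2, 3, 4, 6, 7; attempts: levels 1, 2, 3, 5, 6, 7
  for (l in c(2, 3, 4, 6, 7)) {
    s <- summary_from_stats(tab$time_mean[l], tab$time_sd[l], 25)
    expect_equal(format_ci(s), tab$time_ci[l])
  }
  for (l in c(1, 2, 3, 5, 6, 7)) {
    s <- summary_from_stats(tab$attempts_mean[l], tab$attempts_sd[l], 25)
    expect_equal(format_ci(s), tab$attempts_ci[l])
  }
  expect_equal(format_p(0.0004), "<.001")
  expect_equal(format_p(0.0096), ".010")
  expect_equal(format_p(0.23), ".230")
})
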