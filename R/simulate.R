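#' Simulated-player model parameters
#'
#' A transparent generative stand-in for human performance. Completion time
#' is lognormal with additive effects on the log scale:
#' \deqn{\log T = \alpha_{level} + \beta_{fov} 1[limited] + u + \epsilon}
#' with participant effect \eqn{u \sim N(0, participant\_sd^2)} and trial
#' noise \eqn{\epsilon \sim N(0, \sigma^2)}. Attempts are
#' `1 + Poisson(lambda_err)`, independent of the field of view — the model
#' deliberately encodes the study's two findings: a multiplicative FOV
#' effect on time and no FOV effect on attempts.
#'
#' Defaults: the per-level baselines `alpha_level` are calibrated so the
#' noiseless means reproduce the published per-level mean times
#' (5.7, 3.3, 7.2, 6.4, 12.5, 9.8, 16.4 s), and `beta_fov` defaults to
#' `log(12.5/6.4)` (~0.669), the log ratio of the matched level pair 4/5.
#'
#' @param beta_fov Additive log-time effect of the limited field of view.
#' @param alpha_level Base log-times for levels 1..7. `NULL` (default)
#'   calibrates them from the published level means and `beta_fov`.
#' @param gamma_vessels,gamma_intertwined Optional extra additive log-time
#'   effects per additional vessel / for intertwining; default 0 because the
#'   per-level baselines already absorb level structure.
#' @param sigma Within-participant log-time SD (default 0.35).
#' @param lambda_err Expected extra failed attempts per trial (default 0.5,
#'   matching published mean attempts of 1.2-1.8).
#' @param participant_sd Between-participant log-time SD (default 0.30).
#' @return A list of class `vg_params`.
#' @export
player_params <- function(beta_fov = log(12.5 / 6.4), alpha_level = NULL,
                          gamma_vessels = 0, gamma_intertwined = 0,
                          sigma = 0.35, lambda_err = 0.5,
                          participant_sd = 0.30) {
  if (sigma < 0 || lambda_err < 0 || participant_sd < 0)
    vg_stop("sigma, lambda_err and participant_sd must be non-negative",
            "vg_config_error")
  if (is.null(alpha_level)) {
    means <- c(5.7, 3.3, 7.2, 6.4, 12.5, 9.8, 16.4)
    limited <- level_table()$fov_mode == "limited"
    alpha_level <- log(means) - beta_fov * limited
  }
  if (length(alpha_level) != 7L)
    vg_stop("alpha_level must have 7 entries (one per level)",
            "vg_config_error")
  structure(
    list(alpha_level = as.double(alpha_level), beta_fov = beta_fov,
         gamma_vessels = gamma_vessels,
         gamma_intertwined = gamma_intertwined,
         sigma = sigma, lambda_err = lambda_err,
         participant_sd = participant_sd),
    class = "vg_params"
  )
}

trial_log_mean <- function(spec, params, participant_effect = 0) {
  params$alpha_level[spec$level_id] +
    params$beta_fov * (spec$fov_mode == "limited") +
    params$gamma_vessels * (spec$n_vessels - 1L) +
    params$gamma_intertwined * spec$intertwined +
    participant_effect
}

#' Simulate one trial outcome
#'
#' Draws one completed trial from the generative model (see
#' [player_params()]), using the current RNG stream.
#'
#' @param spec A [make_level_spec()].
#' @param params A [player_params()].
#' @param participant_effect The participant's log-time offset.
#' @param participant_id Optional id for the record.
#' @return A one-row trial record data frame.
#' @export
simulate_trial <- function(spec, params = player_params(),
                           participant_effect = 0,
                           participant_id = NA_character_) {
  mu <- trial_log_mean(spec, params, participant_effect)
  data.frame(
    participant_id = participant_id,
    level_id = spec$level_id,
    fov_mode = spec$fov_mode,
    time_s = exp(mu + stats::rnorm(1, 0, params$sigma)),
    attempts = 1L + stats::rpois(1, params$lambda_err),
    success = TRUE,
    seed = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of participants
#'
#' Each participant gets one draw of the between-participant effect and
#' plays the 7 levels in order (the fixed ladder keeps players in flow, so
#' order is never randomised). All randomness flows from `seed`.
#'
#' @param n_participants Number of simulated participants, >= 2.
#' @param params A [player_params()].
#' @param seed Master seed.
#' @return A list of class `vg_cohort` with `trials` (data frame of
#'   `n_participants * 7` trial records), `params`, `seed`.
#' @export
#' @examples
#' co <- simulate_cohort(25, seed = 1)
#' nrow(co$trials)
simulate_cohort <- function(n_participants, params = player_params(),
                            seed = 1L) {
  if (n_participants < 2L)
    vg_stop("need at least 2 participants", "vg_config_error")
  set.seed(as.integer(seed))
  lt <- level_table()
  n <- as.integer(n_participants)
  u <- stats::rnorm(n, 0, params$participant_sd)
  grid <- expand.grid(level_id = lt$level_id, participant = seq_len(n))
  grid <- grid[order(grid$participant, grid$level_id), ]
  mu <- params$alpha_level[grid$level_id] +
    params$beta_fov * (lt$fov_mode[grid$level_id] == "limited") +
    params$gamma_vessels * (lt$n_vessels[grid$level_id] - 1L) +
    params$gamma_intertwined * lt$intertwined[grid$level_id] +
    u[grid$participant]
  m <- nrow(grid)
  trials <- data.frame(
    participant_id = sprintf("P%03d", grid$participant),
    level_id = grid$level_id,
    fov_mode = lt$fov_mode[grid$level_id],
    time_s = exp(mu + stats::rnorm(m, 0, params$sigma)),
    attempts = 1L + stats::rpois(m, params$lambda_err),
    success = TRUE,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  rownames(trials) <- NULL
  structure(list(trials = trials, params = params, seed = as.integer(seed)),
            class = "vg_cohort")
}

#' @export
print.vg_cohort <- function(x, ...) {
  cat(sprintf("<vg_cohort> %d trials, %d participants, seed %d\n",
              nrow(x$trials), length(unique(x$trials$participant_id)),
              x$seed))
  invisible(x)
}

#' Estimate the FOV effect from a cohort
#'
#' Estimates the additive log-time effect of the limited field of view from
#' the matched level pairs (default 4 vs 5 and 6 vs 7): for each participant
#' the mean of `log(t_limited) - log(t_full)` over the pairs, then a
#' one-sample t interval over participants. Unbiased when the paired levels
#' share the same baseline apart from the FOV (the design intent of the
#' matched pairs).
#'
#' @param cohort A `vg_cohort` or a trials data frame.
#' @param pairs List of `c(full_level, limited_level)` pairs.
#' @param conf Confidence level.
#' @return List with `estimate`, `se`, `df`, `ci_low`, `ci_high`.
#' @export
estimate_fov_effect <- function(cohort, pairs = list(c(4, 5), c(6, 7)),
                                conf = 0.95) {
  trials <- if (inherits(cohort, "vg_cohort")) cohort$trials else cohort
  ids <- unique(trials$participant_id)
  diffs <- vapply(ids, function(pid) {
    tt <- trials[trials$participant_id == pid, ]
    mean(vapply(pairs, function(pr) {
      log(tt$time_s[tt$level_id == pr[2L]]) -
        log(tt$time_s[tt$level_id == pr[1L]])
    }, numeric(1)))
  }, numeric(1))
  n <- length(diffs)
  est <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 1L)
  list(estimate = est, se = se, df = n - 1L,
       ci_low = est - tq * se, ci_high = est + tq * se)
}

## ---------------------------------------------------------------------------
## Mechanistic agent: scan, locate the black markers, trace, cut.

#' Play a scene with a mechanistic agent
#'
#' Produces a pointer-event stream that, replayed through the engine,
#' completes the level. Under a full field of view the agent moves straight
#' to the target and cuts. Under a limited field of view it scans the scene
#' in a boustrophedon (serpentine) sweep with row stride no larger than the
#' spotlight radius until both black markers have been inside the spotlight,
#' then traces to the target and cuts — so locate time scales with scene
#' area over spotlight area. With `aim_noise > 0` the cut placement is
#' perturbed and failed attempts occur naturally.
#'
#' @param scene A `vg_scene`.
#' @param fov_mode,fov_radius Field-of-view configuration.
#' @param policy List of motor parameters: `move_speed` (units/s, default
#'   600), `scan_speed` (default 700), `react` (pause before cutting,
#'   default 0.15 s), `aim_noise` (SD of cut placement jitter in units,
#'   default 0), `max_attempts` (default 10).
#' @param seed Optional seed for the agent's noise.
#' @param config A [run_config()].
#' @return An event data frame suitable for [replay()].
#' @export
agent_play <- function(scene, fov_mode = c("full", "limited"),
                       fov_radius = config$fov_radius, policy = list(),
                       seed = NULL, config = run_config()) {
  fov_mode <- match.arg(fov_mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pol <- utils::modifyList(
    list(move_speed = 600, scan_speed = 700, react = 0.15,
         aim_noise = 0, max_attempts = 10L), policy)
  target <- scene$vessels[[scene$target_index]]
  cl <- as_point_matrix(target$centerline)
  m <- nrow(cl)
  half <- target$width / 2 + min(13, (config$l_max - target$width) / 2)

  plan_cut <- function(jitter_sd = 0) {
    order_idx <- order(abs(seq_len(m) - m / 2))  # mid outward
    for (i in order_idx[seq(2, length(order_idx) - 1)]) {
      p <- cl[i, ]
      tang <- cl[min(i + 1L, m), ] - cl[max(i - 1L, 1L), ]
      nrm <- c(-tang[2L], tang[1L]) / sqrt(sum(tang^2))
      a <- p - half * nrm; b <- p + half * nrm
      if (jitter_sd > 0) {
        a <- a + stats::rnorm(2, 0, jitter_sd)
        b <- b + stats::rnorm(2, 0, jitter_sd)
      }
      inside <- function(q) q[1L] >= 0 && q[1L] <= scene$width &&
        q[2L] >= 0 && q[2L] <= scene$height
      if (!inside(a) || !inside(b)) next
      if (jitter_sd > 0) return(list(a = a, b = b))
      if (is_cut(cut_line(a, b), target,
                 strict_sides = config$strict_sides))
        return(list(a = a, b = b))
    }
    # fall back to the midpoint even if unverified
    p <- cl[ceiling(m / 2), ]
    tang <- cl[min(ceiling(m / 2) + 1L, m), ] - cl[max(ceiling(m / 2) - 1L, 1L), ]
    nrm <- c(-tang[2L], tang[1L]) / sqrt(sum(tang^2))
    list(a = p - half * nrm, b = p + half * nrm)
  }

  events <- list()
  t <- 0
  cursor <- c(scene$width / 2, scene$height / 2)
  emit <- function(kind, p, dt) {
    t <<- t + dt
    events[[length(events) + 1L]] <<- data.frame(
      t = t, kind = kind, x = p[1L], y = p[2L], stringsAsFactors = FALSE)
    cursor <<- p
  }
  move_to <- function(p, speed) {
    d <- sqrt(sum((p - cursor)^2))
    emit("move", p, d / speed)
  }

  if (fov_mode == "limited") {
    # serpentine sweep, row stride <= fov_radius
    stride <- 0.9 * fov_radius
    rows <- seq(stride / 2, scene$height, by = stride)
    xs <- seq(0, scene$width, by = fov_radius / 2)
    marks <- scene$markers[scene$markers$black, , drop = FALSE]
    seen <- rep(FALSE, nrow(marks))
    done <- FALSE
    for (ri in seq_along(rows)) {
      xr <- if (ri %% 2L == 1L) xs else rev(xs)
      for (x in xr) {
        p <- c(x, rows[ri])
        move_to(p, pol$scan_speed)
        d <- sqrt((marks$x - p[1L])^2 + (marks$y - p[2L])^2)
        seen <- seen | d <= fov_radius
        if (all(seen)) { done <- TRUE; break }
      }
      if (done) break
    }
  }

  for (attempt in seq_len(pol$max_attempts)) {
    cut <- plan_cut(jitter_sd = pol$aim_noise)
    move_to(cut$a, pol$move_speed)
    emit("press", cut$a, pol$react)
    mid <- (cut$a + cut$b) / 2
    emit("drag", mid, sqrt(sum((mid - cut$a)^2)) / pol$move_speed)
    emit("drag", cut$b, sqrt(sum((cut$b - mid)^2)) / pol$move_speed)
    emit("release", cut$b, 0.02)
    line <- cut_line(cut$a, clamp_to_length(cut$a, cut$b, config$l_max))
    if (is_cut(line, target, strict_sides = config$strict_sides)) break
  }
  do.call(rbind, events)
}
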