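#' Construct a cut line
#'
#' @param start,end Points `c(x, y)`.
#' @return List of class `vg_cut_line` with `start` and `end`.
#' @export
cut_line <- function(start, end) {
  structure(list(start = as.double(start), end = as.double(end)),
            class = "vg_cut_line")
}

line_length <- function(line) sqrt(sum((line$end - line$start)^2))

## Pull `end` back onto the circle of radius l_max around `start`.
clamp_to_length <- function(start, end, l_max) {
  d <- sqrt(sum((end - start)^2))
  if (d <= l_max) return(as.double(end))
  as.double(start + (end - start) * (l_max / d))
}

#' Pointer event
#'
#' One mouse event of the interaction stream: `move` (cursor/viewport
#' motion), `press` (start drawing a line), `drag` (extend the line while
#' the button is held) or `release` (finish the line; one attempt).
#'
#' @param t Seconds since session start.
#' @param kind One of `"move"`, `"press"`, `"drag"`, `"release"`.
#' @param x,y Pointer position.
#' @return List of class `vg_event`.
#' @export
pointer_event <- function(t, kind, x, y) {
  kind <- match.arg(kind, c("move", "press", "drag", "release"))
  structure(list(t = as.double(t), kind = kind,
                 x = as.double(x), y = as.double(y)),
            class = "vg_event")
}

#' Start a game session
#'
#' The timer starts at session creation (the original started it when the
#' level was clicked). Time is driven by the `t` stamps on pointer events;
#' an optional injected clock lets interactive front ends poll elapsed time
#' without events.
#'
#' @param scene A [generate_scene()] scene.
#' @param fov_mode `"full"` or `"limited"`.
#' @param fov_radius Spotlight radius, required > 0 in limited mode.
#' @param clock Optional zero-argument function returning monotonic seconds.
#' @param paint If `TRUE`, enables the "paint" mosaicking mode in which
#'   [reveal()]ed regions stay visible.
#' @param config A [run_config()]; supplies `l_max` and `strict_sides`.
#' @return A list of class `vg_session`.
#' @export
new_session <- function(scene, fov_mode = c("full", "limited"),
                        fov_radius = config$fov_radius, clock = NULL,
                        paint = FALSE, config = run_config()) {
  fov_mode <- match.arg(fov_mode)
  if (fov_mode == "limited" && (!is.finite(fov_radius) || fov_radius <= 0))
    vg_stop("limited field of view needs a positive radius",
            "vg_config_error")
  structure(
    list(scene = scene, fov_mode = fov_mode, fov_radius = fov_radius,
         cursor = c(scene$width / 2, scene$height / 2),
         active_line = NULL, attempts = 0L, elapsed = 0,
         completed = FALSE, time_s = NA_real_,
         paint = isTRUE(paint), revealed = list(),
         ignored_events = 0L, last_result = NULL,
         l_max = config$l_max, strict_sides = config$strict_sides,
         clock = clock,
         t0 = if (!is.null(clock)) clock() else NULL),
    class = "vg_session"
  )
}

#' Is a point visible to the player?
#'
#' Full mode: everything is visible. Limited mode: only points within
#' `fov_radius` of the cursor (the spotlight follows the mouse, with the
#' pointer at the centre of the viewport), plus any region revealed in
#' paint mode.
#'
#' @param state A `vg_session`.
#' @param p Point `c(x, y)`.
#' @return `TRUE` or `FALSE`.
#' @export
visible <- function(state, p) {
  if (state$fov_mode == "full") return(TRUE)
  p <- as.double(p)
  if (sqrt(sum((p - state$cursor)^2)) <= state$fov_radius) return(TRUE)
  for (r in state$revealed) {
    if (sqrt(sum((p - r$center)^2)) <= r$radius) return(TRUE)
  }
  FALSE
}

#' Permanently reveal a region (paint/mosaicking mode)
#'
#' Adds a spotlight-sized disc at `p` to the set of permanently visible
#' regions, emulating computational mosaicking of previously seen views.
#'
#' @param state A `vg_session` created with `paint = TRUE`.
#' @param p Centre of the revealed disc.
#' @return The updated session.
#' @export
reveal <- function(state, p) {
  if (!state$paint)
    vg_stop("paint mode is not enabled for this session", "vg_config_error")
  state$revealed <- c(state$revealed,
                      list(list(center = as.double(p),
                                radius = state$fov_radius)))
  state
}

#' Evaluate a finished cut line
#'
#' Success requires fully transecting the target vessel (the one with two
#' black endpoint circles). Cutting any other vessel is recorded but is a
#' failed attempt: the attempt counter was already incremented and the timer
#' keeps running.
#'
#' @param state A `vg_session`.
#' @param line A [cut_line()].
#' @return List of class `vg_attempt` with `success`, `line`,
#'   `cut_vessel_index` (`NA` if nothing was cut), `attempts_so_far`.
#' @export
evaluate_release <- function(state, line) {
  scene <- state$scene
  cut_idx <- NA_integer_
  success <- FALSE
  if (is_cut(line, scene$vessels[[scene$target_index]],
             strict_sides = state$strict_sides)) {
    cut_idx <- scene$target_index
    success <- TRUE
  } else {
    for (i in seq_along(scene$vessels)) {
      if (i == scene$target_index) next
      if (is_cut(line, scene$vessels[[i]],
                 strict_sides = state$strict_sides)) { cut_idx <- i; break }
    }
  }
  structure(list(success = success, line = line,
                 cut_vessel_index = cut_idx,
                 attempts_so_far = state$attempts),
            class = "vg_attempt")
}

#' Apply one pointer event to a session
#'
#' `move`/`drag` update the cursor (and spotlight); `press` opens a line at
#' the pointer; `drag` extends the line's end, clamped so its length never
#' exceeds `l_max` (45 units by default) by pulling the end back onto the
#' circle around the start; `release` closes the line, increments the
#' attempt counter, evaluates the cut, and on success freezes the timer.
#' Events after completion are ignored (counted in `ignored_events`).
#'
#' @param state A `vg_session`.
#' @param e A [pointer_event()].
#' @return The updated session.
#' @export
apply_event <- function(state, e) {
  if (state$completed) {
    state$ignored_events <- state$ignored_events + 1L
    return(state)
  }
  if (e$t < state$elapsed)
    vg_stop(sprintf("event at t=%g precedes current elapsed time %g",
                    e$t, state$elapsed), "vg_protocol_error")
  state$elapsed <- e$t
  pos <- c(e$x, e$y)
  switch(e$kind,
    move = {
      state$cursor <- pos
    },
    press = {
      if (!is.null(state$active_line))
        vg_stop("press while a line is already being drawn",
                "vg_protocol_error")
      state$cursor <- pos
      state$active_line <- cut_line(pos, pos)
    },
    drag = {
      state$cursor <- pos
      if (!is.null(state$active_line)) {
        state$active_line$end <-
          clamp_to_length(state$active_line$start, pos, state$l_max)
      }
    },
    release = {
      if (is.null(state$active_line))
        vg_stop("release without a preceding press", "vg_protocol_error")
      state$cursor <- pos
      state$active_line$end <-
        clamp_to_length(state$active_line$start, pos, state$l_max)
      line <- state$active_line
      state$active_line <- NULL
      state$attempts <- state$attempts + 1L
      res <- evaluate_release(state, line)
      res$attempts_so_far <- state$attempts
      state$last_result <- res
      if (res$success) {
        state$completed <- TRUE
        state$time_s <- state$elapsed
      }
    },
    vg_stop(sprintf("unknown event kind '%s'", e$kind), "vg_protocol_error")
  )
  state
}

#' Replay an event stream deterministically
#'
#' Runs a full session over a time-ordered pointer-event stream and returns
#' the trial outcome. Identical inputs always give identical records, which
#' is the package's main test surface for engine determinism.
#'
#' @param scene A `vg_scene`.
#' @param events A data frame with columns `t`, `kind`, `x`, `y` (as
#'   written/read by [write_events()]), or a list of [pointer_event()]s.
#' @param fov_mode,fov_radius,config Session configuration, see
#'   [new_session()].
#' @param participant_id Optional id copied into the record.
#' @return A one-row data frame (a trial record) with columns
#'   `participant_id`, `level_id`, `fov_mode`, `time_s`, `attempts`,
#'   `success`, `seed`.
#' @export
replay <- function(scene, events, fov_mode = c("full", "limited"),
                   fov_radius = config$fov_radius,
                   participant_id = NA_character_,
                   config = run_config()) {
  fov_mode <- match.arg(fov_mode)
  events <- as_event_frame(events)
  state <- new_session(scene, fov_mode, fov_radius, config = config)
  if (nrow(events) > 0L) {
    if (is.unsorted(events$t))
      vg_stop("event stream is not time-ordered", "vg_protocol_error")
    for (i in seq_len(nrow(events))) {
      e <- pointer_event(events$t[i], events$kind[i],
                         events$x[i], events$y[i])
      state <- tryCatch(
        apply_event(state, e),
        vg_protocol_error = function(cnd) {
          vg_stop(sprintf("malformed event stream at index %d: %s",
                          i, conditionMessage(cnd)), "vg_protocol_error")
        })
    }
  }
  data.frame(
    participant_id = participant_id,
    level_id = scene$level_id,
    fov_mode = fov_mode,
    time_s = if (state$completed) state$time_s else state$elapsed,
    attempts = state$attempts,
    success = state$completed,
    seed = scene$seed,
    stringsAsFactors = FALSE
  )
}

as_event_frame <- function(events) {
  if (is.data.frame(events)) {
    need <- c("t", "kind", "x", "y")
    miss <- setdiff(need, names(events))
    if (length(miss))
      vg_stop(paste("event stream lacks columns:",
                    paste(miss, collapse = ", ")), "vg_schema_error")
    return(events)
  }
  if (inherits(events, "vg_event")) events <- list(events)
  do.call(rbind, lapply(events, function(e)
    data.frame(t = e$t, kind = e$kind, x = e$x, y = e$y,
               stringsAsFactors = FALSE))) %||%
    data.frame(t = numeric(), kind = character(),
               x = numeric(), y = numeric())
}

#' Read or write a pointer-event stream as JSONL
#'
#' One event per line: `{"t":..., "kind":"...", "x":..., "y":...}`.
#'
#' @param events Event data frame or list of [pointer_event()]s.
#' @param path File path.
#' @return `read_events()` returns an event data frame; `write_events()` the
#'   path, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_frame(events)
  lines <- vapply(seq_len(nrow(events)), function(i) {
    as.character(jsonlite::toJSON(
      list(t = events$t[i], kind = events$kind[i],
           x = events$x[i], y = events$y[i]),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(t = numeric(), kind = character(),
                      x = numeric(), y = numeric()))
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(cnd)
                      vg_stop(sprintf("malformed event at line %d", i),
                              "vg_protocol_error"))
    data.frame(t = as.double(obj$t), kind = as.character(obj$kind),
               x = as.double(obj$x), y = as.double(obj$y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
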