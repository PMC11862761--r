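#' Generate a wavy vessel centerline
#'
#' Places `n_waypoints` waypoints at equally spaced x positions spanning the
#' full scene width, draws their y coordinates as a common base level plus
#' uniform jitter inside a vertical band, and interpolates with a natural
#' cubic spline sampled at `n_samples` points. The first point has x = 0 and
#' the last x = `width`, so every vessel stretches across the whole window.
#'
#' @param width,height Scene size, > 0.
#' @param n_waypoints Number of spline waypoints, >= 2.
#' @param seed Optional integer; when given, seeds the RNG so the same seed
#'   reproduces the same centerline. When `NULL` the current RNG stream is
#'   used (this is how [generate_scene()] keeps all randomness under one
#'   master seed).
#' @param y_range Vertical band `c(lo, hi)` the curve must stay inside;
#'   defaults to `margin .. height - margin`.
#' @param y_jitter Half-width of the uniform jitter applied to each
#'   waypoint's y around the common base level. `0` gives a straight
#'   horizontal line. Default: 35% of the band height.
#' @param margin Vertical margin used for the default `y_range`.
#' @param n_samples Number of points the spline is sampled at.
#' @return An `n_samples` x 2 matrix of points.
#' @export
generate_centerline <- function(width, height, n_waypoints = 6, seed = NULL,
                                y_range = NULL, y_jitter = NULL,
                                margin = 40, n_samples = 100) {
  stopifnot(width > 0, height > 0, n_waypoints >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(y_range)) y_range <- c(margin, height - margin)
  if (is.null(y_jitter)) y_jitter <- 0.35 * diff(y_range)
  base_y <- stats::runif(1, y_range[1L], y_range[2L])
  wx <- seq(0, width, length.out = n_waypoints)
  wy <- base_y + stats::runif(n_waypoints, -y_jitter, y_jitter)
  wy <- pmin(pmax(wy, y_range[1L]), y_range[2L])
  s <- stats::spline(wx, wy, method = "natural",
                     xout = seq(0, width, length.out = n_samples))
  cbind(s$x, pmin(pmax(s$y, y_range[1L]), y_range[2L]))
}

#' Generate a reproducible vessel scene
#'
#' Builds the playfield for one level: `n_vessels` red vessel bands spanning
#' the window width over a low-contrast background, endpoint circles on
#' every vessel, and exactly one target vessel whose two circles are black.
#' Non-intertwined levels place each vessel in its own horizontal band so
#' centerlines never cross; intertwined levels rejection-sample full-band
#' splines until every vessel pair crosses at least `k_min` times (and all
#' stroked polygons are simple), bounded by `retry_cap` retries.
#'
#' @param spec A [make_level_spec()] result (or a level id 1..7).
#' @param width,height Scene size; default from `config`.
#' @param seed Master seed; the same `(spec, seed)` always regenerates the
#'   identical scene.
#' @param config A [run_config()].
#' @return A list of class `vg_scene` with fields `width`, `height`, `seed`,
#'   `level_id`, `vessels` (each a list with `centerline`, `width`,
#'   `polygon`, `is_target`), `markers` (data frame `x`, `y`, `r`, `black`),
#'   `target_index`, `palette`.
#' @export
#' @examples
#' sc <- generate_scene(make_level_spec(1), seed = 7)
#' length(sc$vessels)
generate_scene <- function(spec, width = config$width, height = config$height,
                           seed = 1L, config = run_config()) {
  if (is.numeric(spec)) spec <- make_level_spec(spec)
  stopifnot(inherits(spec, "vg_level_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_vessels
  margin <- config$margin
  ok <- FALSE
  for (attempt in seq_len(config$retry_cap)) {
    centerlines <- vector("list", n)
    if (spec$intertwined || n == 1L) {
      for (i in seq_len(n)) {
        centerlines[[i]] <- generate_centerline(
          width, height, n_waypoints = config$n_waypoints,
          margin = margin)
      }
    } else {
      # one disjoint horizontal band per vessel: zero crossings by design
      band_h <- (height - 2 * margin) / n
      pad <- config$vessel_width
      for (i in seq_len(n)) {
        lo <- margin + (i - 1) * band_h + pad
        hi <- margin + i * band_h - pad
        centerlines[[i]] <- generate_centerline(
          width, height, n_waypoints = config$n_waypoints,
          y_range = c(lo, hi))
      }
    }
    crossings_ok <- TRUE
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        k <- count_crossings(centerlines[[i]], centerlines[[j]])
        want <- if (spec$intertwined) k >= config$k_min else k == 0L
        if (!want) { crossings_ok <- FALSE; break }
      }
    }
    if (!crossings_ok) next
    polys <- lapply(centerlines, stroke_polygon, width = config$vessel_width)
    if (all(vapply(polys, polygon_is_simple, logical(1))) &&
        all(vapply(polys, polygon_area, numeric(1)) > 0)) {
      ok <- TRUE
      break
    }
  }
  if (!ok)
    vg_stop(sprintf(
      "scene generation failed after %d retries (infeasible config?)",
      config$retry_cap), "vg_generation_failure")
  target <- sample.int(n, 1L)
  vessels <- lapply(seq_len(n), function(i) {
    list(centerline = centerlines[[i]], width = config$vessel_width,
         polygon = polys[[i]], is_target = (i == target))
  })
  ends <- do.call(rbind, lapply(seq_len(n), function(i) {
    cl <- centerlines[[i]]
    data.frame(x = cl[c(1L, nrow(cl)), 1L], y = cl[c(1L, nrow(cl)), 2L],
               r = config$marker_radius, black = (i == target))
  }))
  rownames(ends) <- NULL
  structure(
    list(width = width, height = height, seed = as.integer(seed),
         level_id = spec$level_id, vessels = vessels, markers = ends,
         target_index = target, palette = config$palette),
    class = "vg_scene"
  )
}

#' @export
print.vg_scene <- function(x, ...) {
  cat(sprintf(
    "<vg_scene> level %d: %d vessel(s) on %g x %g canvas, target #%d, seed %d\n",
    x$level_id, length(x$vessels), x$width, x$height, x$target_index, x$seed))
  invisible(x)
}

## Scene JSON (lossless round trip) -----------------------------------------

scene_to_json <- function(scene) {
  obj <- list(
    width = scene$width, height = scene$height, seed = scene$seed,
    level_id = scene$level_id, target_index = scene$target_index,
    palette = as.list(scene$palette),
    vessels = lapply(scene$vessels, function(v) list(
      centerline = unname(v$centerline), width = v$width,
      polygon = unname(v$polygon), is_target = v$is_target)),
    markers = scene$markers
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "columns")
}

scene_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyMatrix = TRUE)
  vessels <- lapply(seq_along(obj$vessels$width), function(i) list(
    centerline = obj$vessels$centerline[[i]],
    width = obj$vessels$width[[i]],
    polygon = obj$vessels$polygon[[i]],
    is_target = obj$vessels$is_target[[i]]))
  markers <- as.data.frame(obj$markers)
  structure(
    list(width = obj$width, height = obj$height, seed = obj$seed,
         level_id = obj$level_id, vessels = vessels, markers = markers,
         target_index = obj$target_index,
         palette = unlist(obj$palette)),
    class = "vg_scene"
  )
}

#' Read or write a scene as JSON
#'
#' @param scene A `vg_scene`.
#' @param path File path.
#' @return `read_scene()` returns a `vg_scene`; `write_scene()` its path,
#'   invisibly.
#' @export
write_scene <- function(scene, path) {
  writeLines(scene_to_json(scene), path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  scene_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
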