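## 2-D computational geometry primitives.
##
## Coordinates are real-valued scene units with the browser convention:
## origin top-left, x rightward, y downward. Polygons are n x 2 matrices of
## vertices, implicitly closed (last vertex joins back to the first).
## The segment-vs-band cut test is the heart of the game mechanic, so these
## primitives are implemented here rather than delegated; every one of them
## is cross-checked against an independent oracle in the test suite.

.vg_eps <- 1e-9

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    storage.mode(p) <- "double"
    return(p)
  }
  matrix(as.double(unlist(p)), ncol = 2, byrow = TRUE)
}

#' Count transversal crossings between two polylines
#'
#' Counts the proper (transversal) intersection points between two open
#' polylines. This formalises "intertwined": two vessels are intertwined
#' when their centerlines cross at least `k_min` times.
#'
#' @param a,b Polylines as n x 2 matrices (or lists of `c(x, y)` points),
#'   each with at least 2 points.
#' @return Non-negative integer count; symmetric in its arguments.
#' @export
#' @examples
#' count_crossings(rbind(c(0, 0), c(10, 10)), rbind(c(0, 10), c(10, 0)))
count_crossings <- function(a, b) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  if (nrow(a) < 2L || nrow(b) < 2L)
    vg_stop("polylines need at least 2 points", "vg_degenerate_geometry")
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  idx <- expand.grid(i = seq_len(na), j = seq_len(nb))
  p1x <- a[idx$i, 1L]; p1y <- a[idx$i, 2L]
  p2x <- a[idx$i + 1L, 1L]; p2y <- a[idx$i + 1L, 2L]
  q1x <- b[idx$j, 1L]; q1y <- b[idx$j, 2L]
  q2x <- b[idx$j + 1L, 1L]; q2y <- b[idx$j + 1L, 2L]
  # bounding-box prefilter
  keep <- pmax(p1x, p2x) >= pmin(q1x, q2x) & pmin(p1x, p2x) <= pmax(q1x, q2x) &
          pmax(p1y, p2y) >= pmin(q1y, q2y) & pmin(p1y, p2y) <= pmax(q1y, q2y)
  if (!any(keep)) return(0L)
  p1x <- p1x[keep]; p1y <- p1y[keep]; p2x <- p2x[keep]; p2y <- p2y[keep]
  q1x <- q1x[keep]; q1y <- q1y[keep]; q2x <- q2x[keep]; q2y <- q2y[keep]
  d1 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d2 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  d3 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d4 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  sum(d1 * d2 < 0 & d3 * d4 < 0)
}

## Even-odd (ray casting) point-in-polygon, vectorised over query points.
point_in_polygon <- function(px, py, poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Minimum distance from points to the polygon boundary, vectorised.
point_boundary_distance <- function(px, py, poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  best <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1L]; ay <- poly[j, 2L]
    bx <- poly[i, 1L]; by <- poly[i, 2L]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 < .vg_eps) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    ex <- ax + t * dx - px; ey <- ay + t * dy - py
    best <- pmin(best, sqrt(ex * ex + ey * ey))
    j <- i
  }
  best
}

point_strictly_inside <- function(px, py, poly, eps = 1e-7) {
  point_in_polygon(px, py, poly) & point_boundary_distance(px, py, poly) > eps
}

point_strictly_outside <- function(px, py, poly, eps = 1e-7) {
  !point_in_polygon(px, py, poly) & point_boundary_distance(px, py, poly) > eps
}

## Parameters t in [0,1] along segment a->b where it meets polygon edges.
segment_polygon_params <- function(a, b, poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  cx <- poly[, 1L]; cy <- poly[, 2L]
  dx <- poly[c(2:n, 1L), 1L]; dy <- poly[c(2:n, 1L), 2L]
  rx <- b[1L] - a[1L]; ry <- b[2L] - a[2L]
  sx <- dx - cx; sy <- dy - cy
  den <- rx * sy - ry * sx
  ok <- abs(den) > .vg_eps
  t <- ((cx - a[1L]) * sy - (cy - a[2L]) * sx) / den
  u <- ((cx - a[1L]) * ry - (cy - a[2L]) * rx) / den
  hit <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
  sort(t[hit])
}

## Does the open segment a->b properly cross any of the given edges?
## edges: list of (2 x 2) matrices.
segment_hits_chain <- function(a, b, chain) {
  n <- nrow(chain)
  if (n < 2L) return(FALSE)
  cx <- chain[-n, 1L]; cy <- chain[-n, 2L]
  dx <- chain[-1L, 1L]; dy <- chain[-1L, 2L]
  rx <- b[1L] - a[1L]; ry <- b[2L] - a[2L]
  sx <- dx - cx; sy <- dy - cy
  den <- rx * sy - ry * sx
  ok <- abs(den) > .vg_eps
  t <- ((cx - a[1L]) * sy - (cy - a[2L]) * sx) / den
  u <- ((cx - a[1L]) * ry - (cy - a[2L]) * rx) / den
  any(ok & t > 0 & t < 1 & u >= 0 & u <= 1)
}

#' Does a cut line fully transect a vessel?
#'
#' A cut counts only when the drawn line enters on one side of the vessel
#' band and exits on the other: both line endpoints must lie strictly
#' outside the vessel polygon and the open segment must pass through the
#' polygon interior. A line with an endpoint inside the band ("failed to
#' completely intersect both sides") is not a cut, and a zero-length line
#' cuts nothing.
#'
#' @param line A list with `start` and `end` points (`c(x, y)`), e.g. from
#'   [cut_line()].
#' @param vessel A vessel as returned inside [generate_scene()] (a list with
#'   a `polygon` matrix), or a bare polygon matrix.
#' @param strict_sides If `TRUE` and the vessel carries stroke structure,
#'   additionally require the segment to cross both long sides of the band,
#'   so a cut exiting through a flat end cap does not count. Default `FALSE`:
#'   end-cap crossings count.
#' @return `TRUE` or `FALSE`.
#' @export
is_cut <- function(line, vessel, strict_sides = FALSE) {
  poly <- if (is.matrix(vessel)) vessel else as_point_matrix(vessel$polygon)
  a <- as.double(line$start); b <- as.double(line$end)
  if (sqrt(sum((b - a)^2)) < .vg_eps) return(FALSE)
  if (!point_strictly_outside(a[1L], a[2L], poly) ||
      !point_strictly_outside(b[1L], b[2L], poly)) return(FALSE)
  ts <- unique(c(0, segment_polygon_params(a, b, poly), 1))
  if (length(ts) < 3L) return(FALSE)
  mids <- (ts[-1L] + ts[-length(ts)]) / 2
  mx <- a[1L] + mids * (b[1L] - a[1L])
  my <- a[2L] + mids * (b[2L] - a[2L])
  entered <- any(point_strictly_inside(mx, my, poly))
  if (!entered) return(FALSE)
  if (isTRUE(strict_sides) && !is.matrix(vessel) &&
      !is.null(vessel$centerline)) {
    m <- nrow(as_point_matrix(vessel$centerline))
    # stroked ring layout: rows 1..m are one side, m+1..2m the other
    side1 <- poly[seq_len(m), , drop = FALSE]
    side2 <- poly[m + seq_len(m), , drop = FALSE]
    return(segment_hits_chain(a, b, side1) && segment_hits_chain(a, b, side2))
  }
  TRUE
}

#' Stroke a centerline into a vessel polygon
#'
#' Offsets the centerline by half the vessel width on each side (normals
#' from central differences) and closes the band with flat end caps. This
#' is the polygon the cut test runs against.
#'
#' @param centerline n x 2 matrix of points, n >= 2, no consecutive
#'   duplicates.
#' @param width Band width in scene units, > 0.
#' @return A (2n) x 2 matrix: a closed simple ring.
#' @export
#' @examples
#' stroke_polygon(rbind(c(0, 50), c(100, 50)), 20)
stroke_polygon <- function(centerline, width) {
  cl <- as_point_matrix(centerline)
  m <- nrow(cl)
  if (m < 2L) vg_stop("centerline needs at least 2 points",
                      "vg_degenerate_geometry")
  if (width <= 0) vg_stop("width must be positive", "vg_degenerate_geometry")
  seg <- diff(cl)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen < .vg_eps))
    vg_stop("centerline has consecutive duplicate points",
            "vg_degenerate_geometry")
  # tangent at each point: one-sided at the ends, central in the middle
  tx <- numeric(m); ty <- numeric(m)
  tx[1L] <- seg[1L, 1L]; ty[1L] <- seg[1L, 2L]
  tx[m] <- seg[m - 1L, 1L]; ty[m] <- seg[m - 1L, 2L]
  if (m > 2L) {
    tx[2:(m - 1L)] <- cl[3:m, 1L] - cl[1:(m - 2L), 1L]
    ty[2:(m - 1L)] <- cl[3:m, 2L] - cl[1:(m - 2L), 2L]
  }
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl
  h <- width / 2
  lower <- cbind(cl[, 1L] - h * nx, cl[, 2L] - h * ny)
  upper <- cbind(cl[, 1L] + h * nx, cl[, 2L] + h * ny)
  ring <- rbind(lower, upper[m:1, , drop = FALSE])
  dimnames(ring) <- NULL
  ring
}

## Shoelace area (absolute).
polygon_area <- function(poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

## Simplicity: no two non-adjacent edges properly intersect.
polygon_is_simple <- function(poly) {
  poly <- as_point_matrix(poly)
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  adjacent <- (j == i + 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  p1x <- poly[i, 1L]; p1y <- poly[i, 2L]
  p2x <- poly[i2[i], 1L]; p2y <- poly[i2[i], 2L]
  q1x <- poly[j, 1L]; q1y <- poly[j, 2L]
  q2x <- poly[i2[j], 1L]; q2y <- poly[i2[j], 2L]
  keep <- pmax(p1x, p2x) >= pmin(q1x, q2x) & pmin(p1x, p2x) <= pmax(q1x, q2x) &
          pmax(p1y, p2y) >= pmin(q1y, q2y) & pmin(p1y, p2y) <= pmax(q1y, q2y)
  if (!any(keep)) return(TRUE)
  p1x <- p1x[keep]; p1y <- p1y[keep]; p2x <- p2x[keep]; p2y <- p2y[keep]
  q1x <- q1x[keep]; q1y <- q1y[keep]; q2x <- q2x[keep]; q2y <- q2y[keep]
  d1 <- (q2x - q1x) * (p1y - q1y) - (q2y - q1y) * (p1x - q1x)
  d2 <- (q2x - q1x) * (p2y - q1y) - (q2y - q1y) * (p2x - q1x)
  d3 <- (p2x - p1x) * (q1y - p1y) - (p2y - p1y) * (q1x - p1x)
  d4 <- (p2x - p1x) * (q2y - p1y) - (p2y - p1y) * (q2x - p1x)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}
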