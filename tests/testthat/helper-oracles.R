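# Independent oracles the implementation is checked against. These
# deliberately use different algorithms from the package internals:
# winding-number point location (vs even-odd ray casting), parametric 2x2
# solves (vs orientation tests), dense segment rasterisation (vs crossing
# parameters), and numerical integration of the t density (vs pt()).

# Winding-number point-in-polygon via summed signed angles.
oracle_point_in_polygon <- function(p, poly) {
  vx <- poly[, 1] - p[1]
  vy <- poly[, 2] - p[2]
  n <- nrow(poly)
  a1 <- atan2(vy, vx)
  a2 <- atan2(vy[c(2:n, 1)], vx[c(2:n, 1)])
  d <- a2 - a1
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
}

# Brute-force transversal crossing count: solve every segment pair.
oracle_count_crossings <- function(a, b) {
  count <- 0L
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      r <- a[i + 1, ] - a[i, ]
      s <- b[j + 1, ] - b[j, ]
      den <- r[1] * s[2] - r[2] * s[1]
      if (abs(den) < 1e-12) next
      q <- b[j, ] - a[i, ]
      t <- (q[1] * s[2] - q[2] * s[1]) / den
      u <- (q[1] * r[2] - q[2] * r[1]) / den
      if (t > 0 && t < 1 && u > 0 && u < 1) count <- count + 1L
    }
  }
  count
}

# Rasterisation oracle for the cut test: sample the segment densely,
# classify each sample with the winding-number rule (summed signed angles,
# vectorised over samples), and demand an interior point with both segment
# ends outside the band.
# Escalates the sampling density until two successive resolutions agree, so
# hairline corner clips are classified correctly without a fixed grid.
oracle_is_cut <- function(a, b, poly) {
  prev <- NA
  for (n_samples in c(1500, 6000, 24000, 96000)) {
    cur <- oracle_is_cut_fixed(a, b, poly, n_samples)
    if (identical(cur, prev)) return(cur)
    prev <- cur
  }
  prev
}

oracle_is_cut_fixed <- function(a, b, poly, n_samples) {
  ts <- seq(0, 1, length.out = n_samples)
  px <- a[1] + ts * (b[1] - a[1])
  py <- a[2] + ts * (b[2] - a[2])
  n <- nrow(poly)
  total <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    d <- atan2(poly[k2, 2] - py, poly[k2, 1] - px) -
      atan2(poly[k, 2] - py, poly[k, 1] - px)
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    total <- total + d
  }
  inside <- abs(total) > pi
  if (inside[1] || inside[n_samples]) return(FALSE)
  any(inside)
}

# Two-sided Welch p by numerical integration of the t density.
oracle_t_p <- function(t_stat, df) {
  2 * stats::integrate(function(x) stats::dt(x, df), abs(t_stat), Inf,
                       rel.tol = 1e-10)$value
}

# Random wavy band fixture for cut-test comparisons: a short random
# polyline stroked to a band, plus a random candidate cut segment nearby.
random_band_case <- function() {
  n <- sample(3:6, 1)
  cl <- cbind(seq(0, 200, length.out = n),
              100 + cumsum(runif(n, -25, 25)))
  w <- runif(1, 8, 24)
  poly <- stroke_polygon(cl, w)
  mid <- cl[sample(seq_len(n), 1), ] + runif(2, -w, w)
  ang <- runif(1, 0, 2 * pi)
  len <- runif(1, 5, 45)
  a <- mid + (len / 2) * c(cos(ang), sin(ang))
  b <- mid - (len / 2) * c(cos(ang), sin(ang))
  list(a = a, b = b, poly = poly, vessel = list(centerline = cl, width = w,
                                               polygon = poly))
}

# Synthesize n values with an exact sample mean and SD.
values_with_stats <- function(mean, sd, n) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# Vectorised simulated power of the Welch test on N(0,1) vs N(d,1).
simulated_welch_power <- function(n, d, reps, alpha = 0.05) {
  x <- matrix(stats::rnorm(n * reps), nrow = reps)
  y <- matrix(stats::rnorm(n * reps, mean = d), nrow = reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  se2 <- vx / n + vy / n
  tt <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  mean(p < alpha)
}
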