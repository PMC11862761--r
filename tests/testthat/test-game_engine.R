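# A fixed horizontal-band scene makes engine behaviour easy to reason
# about: one vessel, band y in [293, 307] across an 800-wide canvas.
flat_scene <- function(n_vessels = 1, target = 1, ys = c(300, 150, 450)) {
  vessels <- lapply(seq_len(n_vessels), function(i) {
    cl <- cbind(seq(0, 800, length.out = 50), ys[i])
    list(centerline = cl, width = 14, polygon = stroke_polygon(cl, 14),
         is_target = (i == target))
  })
  markers <- do.call(rbind, lapply(seq_len(n_vessels), function(i)
    data.frame(x = c(0, 800), y = ys[i], r = 8, black = (i == target))))
  structure(list(width = 800, height = 600, seed = 0L, level_id = 1L,
                 vessels = vessels, markers = markers, target_index = target,
                 palette = c(background = "#CD5C5C", vessel = "#B22222")),
            class = "vg_scene")
}

test_that("new sessions start clean and full FOV sees everything", {
  st <- new_session(flat_scene(), "full")
  expect_equal(st$attempts, 0L)
  expect_false(st$completed)
  expect_equal(st$elapsed, 0)
  set.seed(1)
  for (i in 1:20) expect_true(visible(st, runif(2, 0, 600)))
  expect_error(new_session(flat_scene(), "limited", fov_radius = 0),
               class = "vg_config_error")
})

test_that("limited FOV is a cursor-centred disc", {
  st <- new_session(flat_scene(), "limited", fov_radius = 100)
  st$cursor <- c(400, 300)
  expect_true(visible(st, c(400, 300)))
  expect_true(visible(st, c(499.9, 300)))
  expect_false(visible(st, c(500.1, 300)))
  # fraction of a dense grid visible ~ pi r^2 / (W H), within 2%
  gx <- seq(0.5, 799.5, by = 4); gy <- seq(0.5, 599.5, by = 4)
  grid <- expand.grid(x = gx, y = gy)
  vis <- sqrt((grid$x - 400)^2 + (grid$y - 300)^2) <= 100
  expect_equal(mean(vis), pi * 100^2 / (800 * 600), tolerance = 0.02)
})

test_that("drag clamps the line to the 45-unit cap", {
  st <- new_session(flat_scene(), "full")
  st <- apply_event(st, pointer_event(0.1, "press", 10, 10))
  st <- apply_event(st, pointer_event(0.2, "drag", 100, 10))
  expect_equal(st$active_line$end, c(55, 10))
  # property: no drag can ever exceed the cap
  set.seed(3)
  for (i in 1:200) {
    st <- apply_event(st, pointer_event(0.2 + i / 100, "drag",
                                        runif(1, -500, 1300),
                                        runif(1, -500, 1100)))
    len <- sqrt(sum((st$active_line$end - st$active_line$start)^2))
    expect_lte(len, 45 + 1e-9)
  }
})

test_that("releases count attempts; zero-length lines cut nothing", {
  st <- new_session(flat_scene(), "full")
  st <- apply_event(st, pointer_event(0.5, "press", 200, 200))
  st <- apply_event(st, pointer_event(0.6, "release", 200, 200))
  expect_equal(st$attempts, 1L)
  expect_false(st$completed)
  expect_false(st$last_result$success)
  expect_true(is.na(st$last_result$cut_vessel_index))
})

test_that("a scripted transection completes the level and freezes time", {
  st <- new_session(flat_scene(), "full")
  st <- apply_event(st, pointer_event(1.0, "move", 400, 280))
  st <- apply_event(st, pointer_event(3.0, "press", 400, 280))
  st <- apply_event(st, pointer_event(3.2, "drag", 400, 310))
  st <- apply_event(st, pointer_event(3.3, "release", 400, 320))
  expect_true(st$completed)
  expect_equal(st$attempts, 1L)
  expect_equal(st$time_s, 3.3)
  # events after completion are ignored, not errors
  st <- apply_event(st, pointer_event(4.0, "press", 1, 1))
  expect_equal(st$ignored_events, 1L)
  expect_equal(st$attempts, 1L)
})

test_that("is_cut requires full transection", {
  band <- stroke_polygon(cbind(seq(0, 100, length.out = 10), 15), 10)
  # band occupies y in [10, 20]
  expect_true(is_cut(cut_line(c(50, 0), c(50, 30)), band))
  expect_false(is_cut(cut_line(c(50, 0), c(50, 15)), band))  # endpoint inside
  expect_false(is_cut(cut_line(c(50, 0), c(50, 8)), band))   # stops short
  expect_false(is_cut(cut_line(c(50, 5), c(50, 5)), band))   # zero length
})

test_that("is_cut agrees with the rasterisation oracle", {
  set.seed(11)
  n_agree <- 0L; n_total <- 400L
  for (i in seq_len(n_total)) {
    cs <- random_band_case()
    got <- is_cut(cut_line(cs$a, cs$b), cs$poly)
    want <- oracle_is_cut(cs$a, cs$b, cs$poly)
    if (got == want) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, n_total)
})

test_that("strict_sides rejects cuts exiting through an end cap", {
  cl <- cbind(seq(0, 100, length.out = 10), 15)
  vessel <- list(centerline = cl, width = 10,
                 polygon = stroke_polygon(cl, 10), is_target = TRUE)
  diag_cap <- cut_line(c(95, 5), c(105, 25))  # through the right cap
  expect_true(is_cut(diag_cap, vessel, strict_sides = FALSE))
  expect_false(is_cut(diag_cap, vessel, strict_sides = TRUE))
  full <- cut_line(c(50, 5), c(50, 25))
  expect_true(is_cut(full, vessel, strict_sides = TRUE))
})

test_that("cutting a non-target vessel is recorded but never succeeds", {
  sc <- flat_scene(n_vessels = 2, target = 1)  # decoy at y=150
  st <- new_session(sc, "full")
  st <- apply_event(st, pointer_event(1, "press", 400, 130))
  st <- apply_event(st, pointer_event(2, "release", 400, 170))
  expect_false(st$completed)
  expect_equal(st$attempts, 1L)
  expect_false(st$last_result$success)
  expect_equal(st$last_result$cut_vessel_index, 2L)
})

test_that("replay is deterministic and validates the stream", {
  sc <- flat_scene()
  ev <- data.frame(
    t = c(0.5, 1.0, 1.2, 1.4),
    kind = c("move", "press", "drag", "release"),
    x = c(300, 400, 400, 400), y = c(100, 280, 300, 320))
  r1 <- replay(sc, ev, fov_mode = "full")
  r2 <- replay(sc, ev, fov_mode = "full")
  expect_identical(r1, r2)
  expect_true(r1$success)
  expect_equal(r1$time_s, 1.4)
  expect_equal(r1$attempts, 1L)

  empty <- replay(sc, ev[0, ], fov_mode = "full")
  expect_equal(empty$attempts, 0L)
  expect_false(empty$success)
  expect_equal(empty$time_s, 0)

  expect_error(replay(sc, ev[c(2, 1, 3, 4), ], fov_mode = "full"),
               class = "vg_protocol_error")
  bad <- ev; bad$kind[1] <- "release"
  expect_error(replay(sc, bad, fov_mode = "full"),
               class = "vg_protocol_error")
})

test_that("timer is monotone and frozen after success", {
  sc <- flat_scene()
  st <- new_session(sc, "full")
  times <- c(0.2, 0.9, 1.5, 2.0)
  kinds <- c("move", "press", "drag", "release")
  xs <- c(100, 400, 400, 400); ys <- c(100, 280, 300, 320)
  last <- 0
  for (i in 1:4) {
    st <- apply_event(st, pointer_event(times[i], kinds[i], xs[i], ys[i]))
    expect_gte(st$elapsed, last)
    last <- st$elapsed
  }
  expect_true(st$completed)
  st <- apply_event(st, pointer_event(9, "move", 0, 0))
  expect_equal(st$time_s, 2.0)
})

test_that("paint mode reveals persistent regions", {
  st <- new_session(flat_scene(), "limited", fov_radius = 50, paint = TRUE)
  st$cursor <- c(700, 500)
  p <- c(100, 100)
  expect_false(visible(st, p))
  st <- reveal(st, p)
  expect_true(visible(st, p))
  # revealed area is monotone, and k disjoint discs have area ~ k * pi r^2
  centers <- list(c(100, 100), c(300, 100), c(500, 100), c(100, 300))
  st2 <- new_session(flat_scene(), "limited", fov_radius = 50, paint = TRUE)
  st2$cursor <- c(799, 599)
  areas <- numeric(0)
  gx <- seq(0.5, 799.5, by = 2); gy <- seq(0.5, 599.5, by = 2)
  grid <- expand.grid(x = gx, y = gy)
  for (k in seq_along(centers)) {
    st2 <- reveal(st2, centers[[k]])
    vis <- rep(FALSE, nrow(grid))
    for (r in st2$revealed) {
      vis <- vis | (sqrt((grid$x - r$center[1])^2 +
                           (grid$y - r$center[2])^2) <= r$radius)
    }
    areas <- c(areas, mean(vis) * 800 * 600)
    expect_equal(areas[k], k * pi * 50^2, tolerance = 0.02)
  }
  expect_true(all(diff(areas) > 0))
  st3 <- new_session(flat_scene(), "limited", fov_radius = 50)
  expect_error(reveal(st3, p), class = "vg_config_error")
})

test_that("event streams round-trip through JSONL", {
  ev <- data.frame(
    t = c(0.123456789, 1), kind = c("move", "press"),
    x = c(10.5, 20.25), y = c(1 / 3, 2))
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_events(ev, tmp)
  back <- read_events(tmp)
  expect_equal(back, ev)
  writeLines(c("{not json"), tmp)
  expect_error(read_events(tmp), class = "vg_protocol_error")
})
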