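#' The 7-level difficulty ladder
#'
#' The game ramps difficulty over seven fixed levels by adding vessels,
#' intertwining them, and restricting the field of view. Two level pairs
#' (4 vs 5 and 6 vs 7) are identical apart from the field of view, which is
#' what makes a within-game FOV comparison possible.
#'
#' @return A data frame with one row per level and columns `level_id`,
#'   `n_vessels`, `intertwined`, `fov_mode`.
#' @export
#' @examples
#' level_table()
level_table <- function() {
  data.frame(
    level_id    = 1:7,
    n_vessels   = c(1L, 2L, 1L, 2L, 2L, 3L, 3L),
    intertwined = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    fov_mode    = c("full", "full", "limited", "full", "limited",
                    "full", "limited"),
    stringsAsFactors = FALSE
  )
}

#' Level specification
#'
#' Look up the fixed design of one game level: how many vessels it shows,
#' whether they are intertwined, and whether the field of view is the full
#' scene or a circular spotlight.
#'
#' @param level_id Integer in 1..7.
#' @return A list of class `vg_level_spec` with fields `level_id`,
#'   `n_vessels`, `intertwined`, `fov_mode`.
#' @export
#' @examples
#' make_level_spec(3)
make_level_spec <- function(level_id) {
  if (length(level_id) != 1L || !is.finite(level_id) ||
      level_id != as.integer(level_id) || level_id < 1 || level_id > 7) {
    vg_stop(sprintf("invalid level id: %s (levels are 1..7)",
                    paste(level_id, collapse = ",")),
            "vg_invalid_level")
  }
  row <- level_table()[as.integer(level_id), ]
  structure(
    list(level_id = row$level_id, n_vessels = row$n_vessels,
         intertwined = row$intertwined, fov_mode = row$fov_mode),
    class = "vg_level_spec"
  )
}

#' @export
print.vg_level_spec <- function(x, ...) {
  cat(sprintf("Level %d: %d vessel(s), %s, %s field of view\n",
              x$level_id, x$n_vessels,
              if (x$intertwined) "intertwined" else "not intertwined",
              x$fov_mode))
  invisible(x)
}
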