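#' Run configuration
#'
#' Bundles every tunable constant of the platform. The single constant fixed
#' by the original game is the 45-unit maximum cut-line length (`l_max`);
#' everything else (canvas size, vessel width, marker radius, spotlight
#' radius, intertwining threshold) was never published and is configurable
#' here, with defaults chosen so that a 45-unit cut comfortably transects
#' one 14-unit-wide vessel on an 800 x 600 canvas.
#'
#' @param width,height Scene size in scene units.
#' @param vessel_width Width of the stroked vessel band.
#' @param marker_radius Radius of the endpoint circles.
#' @param fov_radius Radius of the circular spotlight in limited-FOV mode.
#' @param l_max Maximum cut-line length (45, the one published constant).
#' @param k_min Minimum centerline crossings per vessel pair for a scene to
#'   count as intertwined.
#' @param retry_cap Maximum rejection-sampling retries in
#'   [generate_scene()].
#' @param n_waypoints Spline waypoints per centerline.
#' @param margin Vertical margin keeping vessels away from the canvas edge.
#' @param palette Named character vector `c(background=, vessel=)`;
#'   deliberately low-contrast reds.
#' @param strict_sides Should cuts through a vessel's flat end caps be
#'   rejected? Default `FALSE` (end-cap crossings count).
#' @return A list of class `vg_config`.
#' @export
run_config <- function(width = 800, height = 600,
                       vessel_width = 14, marker_radius = 8,
                       fov_radius = 100, l_max = 45, k_min = 2,
                       retry_cap = 200, n_waypoints = 6, margin = 40,
                       palette = c(background = "#CD5C5C",
                                   vessel = "#B22222"),
                       strict_sides = FALSE) {
  lens <- c(width = width, height = height, vessel_width = vessel_width,
            marker_radius = marker_radius, fov_radius = fov_radius,
            l_max = l_max, margin = margin)
  if (any(!is.finite(lens)) || any(lens <= 0))
    vg_stop("all lengths in the configuration must be positive",
            "vg_config_error")
  structure(
    list(width = width, height = height, vessel_width = vessel_width,
         marker_radius = marker_radius, fov_radius = fov_radius,
         l_max = l_max, k_min = as.integer(k_min),
         retry_cap = as.integer(retry_cap),
         n_waypoints = as.integer(n_waypoints), margin = margin,
         palette = palette, strict_sides = isTRUE(strict_sides)),
    class = "vg_config"
  )
}

## Tiny FNV-1a hash so every report can carry a config fingerprint without
## adding a digest dependency.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h as a double below 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by 16777619, done in two 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_fingerprint <- function(config) {
  fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}
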