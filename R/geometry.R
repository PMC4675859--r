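#' Pool and platform geometry for a Morris water maze
#'
#' Describes the circular pool, the hidden escape platform and the derived
#' analysis zones (peripheral thigmotaxis band, Whishaw corridor width) in a
#' pool-centered coordinate system (cm, x to the east, y to the north).
#'
#' Defaults follow a standard 1.70 m diameter pool with a 12 cm diameter
#' platform whose center sits 22 cm from the wall on the diagonal of the
#' target quadrant. The peripheral band used for thigmotaxis covers the
#' outer 20\% of the pool radius by default; the Whishaw corridor half-width
#' defaults to the platform radius plus 6 cm. Both are analysis conventions
#' rather than physical features and can be changed here in one place.
#'
#' @param pool_radius Pool radius in cm.
#' @param platform_radius Platform radius in cm.
#' @param platform_wall_distance Distance from the pool wall to the platform
#'   center in cm. Ignored when `platform_center` is given.
#' @param target_quadrant One of `"NE"`, `"NW"`, `"SW"`, `"SE"`; the
#'   platform is placed on this quadrant's diagonal.
#' @param platform_center Optional length-2 numeric `(x, y)` overriding the
#'   default placement. Must lie in `target_quadrant`.
#' @param periphery_band_width Width in cm of the peripheral annulus that
#'   counts as thigmotaxis.
#' @param corridor_half_width Half-width in cm of the straight corridor from
#'   release point to goal used by the Whishaw index.
#'
#' @return An object of class `mwm_geometry` (a named list).
#' @export
#' @examples
#' geom <- mwm_geometry()
#' geom$platform_center
mwm_geometry <- function(pool_radius = 85,
                         platform_radius = 6,
                         platform_wall_distance = 22,
                         target_quadrant = c("NE", "NW", "SW", "SE"),
                         platform_center = NULL,
                         periphery_band_width = 0.2 * pool_radius,
                         corridor_half_width = platform_radius + 6) {
  target_quadrant <- match.arg(target_quadrant)
  if (!is.numeric(pool_radius) || length(pool_radius) != 1 || pool_radius <= 0) {
    stop("`pool_radius` must be a single positive number.", call. = FALSE)
  }
  if (platform_radius <= 0) stop("`platform_radius` must be positive.", call. = FALSE)
  if (is.null(platform_center)) {
    r <- pool_radius - platform_wall_distance
    ang <- quadrant_angle(target_quadrant)
    platform_center <- c(r * cos(ang), r * sin(ang))
  }
  platform_center <- as.numeric(platform_center)
  if (length(platform_center) != 2 || any(!is.finite(platform_center))) {
    stop("`platform_center` must be a finite (x, y) pair.", call. = FALSE)
  }
  if (sqrt(sum(platform_center^2)) + platform_radius > pool_radius + 1e-9) {
    stop("Platform must lie entirely inside the pool.", call. = FALSE)
  }
  if (point_quadrant(platform_center[1], platform_center[2]) != target_quadrant) {
    stop("`platform_center` does not lie in `target_quadrant`.", call. = FALSE)
  }
  if (periphery_band_width <= 0 || periphery_band_width >= pool_radius) {
    stop("`periphery_band_width` must be in (0, pool_radius).", call. = FALSE)
  }
  if (corridor_half_width <= 0) stop("`corridor_half_width` must be positive.", call. = FALSE)
  structure(
    list(
      pool_radius = pool_radius,
      platform_radius = platform_radius,
      platform_wall_distance = platform_wall_distance,
      platform_center = platform_center,
      target_quadrant = target_quadrant,
      periphery_band_width = periphery_band_width,
      corridor_half_width = corridor_half_width
    ),
    class = "mwm_geometry"
  )
}

#' @export
print.mwm_geometry <- function(x, ...) {
  cat("<mwm_geometry>\n")
  cat(sprintf("  pool radius:        %.1f cm\n", x$pool_radius))
  cat(sprintf("  platform:           r = %.1f cm at (%.1f, %.1f) [%s]\n",
              x$platform_radius, x$platform_center[1], x$platform_center[2],
              x$target_quadrant))
  cat(sprintf("  periphery band:     %.1f cm\n", x$periphery_band_width))
  cat(sprintf("  corridor half-width:%.1f cm\n", x$corridor_half_width))
  invisible(x)
}

# Diagonal angle (radians) of each quadrant, counterclockwise from east.
quadrant_angle <- function(q) {
  switch(q, NE = pi / 4, NW = 3 * pi / 4, SW = 5 * pi / 4, SE = 7 * pi / 4)
}

#' Quadrant membership of pool-centered points
#'
#' Assigns each point to one of the four quadrants NE, NW, SW, SE. Points
#' exactly on an axis belong to the quadrant that follows counterclockwise
#' (the positive x axis is NE, the positive y axis NW, and so on), so the
#' assignment is deterministic and the four shares always sum to 100\%.
#'
#' @param x,y Numeric vectors of pool-centered coordinates (cm).
#' @return A character vector of quadrant labels.
#' @export
point_quadrant <- function(x, y) {
  ang <- atan2(y, x) %% (2 * pi)
  cut_labels <- c("NE", "NW", "SW", "SE")
  idx <- findInterval(ang, c(0, pi / 2, pi, 3 * pi / 2)) # 1..4, right-open
  cut_labels[idx]
}

# Platform center for reversal sessions: point reflection through the pool
# center ("opposite quadrant").
reversal_platform <- function(geometry) -geometry$platform_center

opposite_quadrant <- function(q) {
  switch(q, NE = "SW", NW = "SE", SW = "NE", SE = "NW")
}
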