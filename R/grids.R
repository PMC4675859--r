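#' Dwell-time occupancy grid of accumulated trajectories
#'
#' Bins the position samples of one or more trials over the pool's bounding
#' square and accumulates dwell time (sample count x sampling interval) per
#' cell, the heat-map representation of accumulated group trajectories.
#' Cells outside the pool disc can only ever hold zero mass because all
#' samples lie inside the pool.
#'
#' @param tracking Long tracking tibble with columns `x`, `y` (and `t`).
#' @param geometry An [mwm_geometry()].
#' @param bin_size Cell edge length in cm.
#' @param dt Sampling interval in seconds (dwell time per sample).
#' @return An object of class `mwm_grid`: list with `counts` (matrix,
#'   rows = x bins), `x_edges`, `y_edges`, `dwell_total` (s), `bin_size`.
#' @export
occupancy_grid <- function(tracking, geometry = mwm_geometry(),
                           bin_size = 5, dt = 0.1) {
  if (nrow(tracking) == 0) stop("Empty tracking input.", call. = FALSE)
  R <- geometry$pool_radius
  edges <- seq(-R, R + bin_size, by = bin_size)
  ix <- findInterval(tracking$x, edges, rightmost.closed = TRUE)
  iy <- findInterval(tracking$y, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  counts <- matrix(0, nb, nb)
  tab <- table(factor(ix, levels = seq_len(nb)), factor(iy, levels = seq_len(nb)))
  counts <- unclass(tab) * dt
  structure(
    list(counts = counts, x_edges = edges, y_edges = edges,
         dwell_total = sum(counts), bin_size = bin_size),
    class = "mwm_grid"
  )
}

#' @export
print.mwm_grid <- function(x, ...) {
  cat("<mwm_grid> ", nrow(x$counts), "x", ncol(x$counts),
      " cells, total dwell ", sprintf("%.1f s\n", x$dwell_total), sep = "")
  invisible(x)
}

#' Plot an occupancy grid as a heat map
#'
#' @param object An `mwm_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwm_grid <- function(object, ...) {
  mids_x <- (object$x_edges[-1] + object$x_edges[-length(object$x_edges)]) / 2
  mids_y <- (object$y_edges[-1] + object$y_edges[-length(object$y_edges)]) / 2
  df <- expand.grid(x = mids_x, y = mids_y)
  df$dwell <- as.vector(object$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dwell)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "dwell (s)") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' Gridded 2D Gaussian kernel density with contour levels
#'
#' Evaluates a bivariate Gaussian kernel density of a point cloud on a
#' regular grid and reports equally spaced contour levels, matching the
#' density-plot conventions of ggplot2's 2D density layer (which this
#' package's plots use with `n = 100`, `h = 5`, 6 bins by default). The
#' grid extends three bandwidths beyond the data range so the density
#' integrates to ~1 over its support.
#'
#' @param points A data frame with numeric columns `x` and `y`.
#' @param grid_n Grid resolution per axis.
#' @param bandwidth Kernel bandwidth `h` passed to [MASS::kde2d()] for both
#'   axes.
#' @param n_levels Number of equally spaced contour levels between 0 and
#'   the density maximum.
#' @return An object of class `mwm_density`: list with `x`, `y` (grid
#'   coordinates), `z` (density matrix), `levels`, and `integral` (the
#'   trapezoidal integral of `z` over the grid).
#' @export
density_grid <- function(points, grid_n = 100, bandwidth = 5, n_levels = 6) {
  if (nrow(points) == 0) stop("Empty point set.", call. = FALSE)
  pad <- 3 * bandwidth
  lims <- c(range(points$x) + c(-pad, pad), range(points$y) + c(-pad, pad))
  kd <- MASS::kde2d(points$x, points$y, h = c(bandwidth, bandwidth),
                    n = grid_n, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  # trapezoidal rule over the grid
  wx <- rep(1, grid_n); wx[c(1, grid_n)] <- 0.5
  integral <- as.numeric(t(wx) %*% kd$z %*% wx) * dx * dy
  levels <- max(kd$z) * seq_len(n_levels) / (n_levels + 1)
  structure(
    list(x = kd$x, y = kd$y, z = kd$z, levels = levels, integral = integral,
         bandwidth = bandwidth),
    class = "mwm_density"
  )
}

#' @export
print.mwm_density <- function(x, ...) {
  cat("<mwm_density> ", length(x$x), "x", length(x$y),
      " grid, integral ", sprintf("%.4f", x$integral),
      ", ", length(x$levels), " levels\n", sep = "")
  invisible(x)
}

#' Plot a kernel density grid with its contour levels
#'
#' @param object An `mwm_density`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mwm_density <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$z <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, z = .data$z)) +
    ggplot2::geom_contour(breaks = object$levels) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1", y = "PC2")
}
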