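#' The seven behavioral variables
#'
#' Column names of the metric set used throughout the package: escape
#' latency (s), Gallagher proximity index (cm), Whishaw corridor index (%),
#' thigmotaxis (%), target-quadrant occupancy (%), path length (cm) and
#' swim speed (cm/s).
#' @export
mwm_metric_vars <- c("latency", "gallagher", "whishaw", "thigmotaxis",
                     "quadrant_time", "distance", "speed")

#' Escape latency and censoring of one trial
#'
#' Latency is the time of the first sample within the platform radius of
#' the platform center; if no sample reaches the platform the trial is
#' censored at its last timestamp (the cutoff for full-length trials).
#'
#' @param t,x,y Numeric vectors: timestamps (s) and pool-centered positions
#'   (cm) of one trial, in order.
#' @param platform_center Platform `(x, y)` in cm.
#' @param platform_radius Platform radius in cm.
#' @return A list with elements `latency` (s) and `censored` (logical).
#' @export
trial_latency <- function(t, x, y, platform_center, platform_radius) {
  if (length(t) == 0) stop("Empty trajectory.", call. = FALSE)
  on_platform <- (x - platform_center[1])^2 + (y - platform_center[2])^2 <=
    platform_radius^2
  hit <- which(on_platform)
  if (length(hit)) {
    list(latency = t[hit[1]], censored = FALSE)
  } else {
    list(latency = t[length(t)], censored = TRUE)
  }
}

#' Swim path length
#'
#' Sum of Euclidean distances between consecutive position samples, in cm.
#'
#' @param x,y Numeric position vectors (cm) of one trial, in order.
#' @return Path length in cm (0 for a single sample).
#' @export
path_length <- function(x, y) {
  n <- length(x)
  if (n < 1) stop("Empty trajectory.", call. = FALSE)
  if (n == 1) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Gallagher proximity index
#'
#' Mean distance between the animal and the goal. Distances are sampled at
#' the tracking rate, averaged within consecutive 1-second blocks, and the
#' block means are then averaged; a trailing partial block is averaged over
#' its own sample count. Lower values indicate search closer to the goal.
#'
#' @param x,y Numeric position vectors (cm), in order.
#' @param goal Goal `(x, y)` in cm.
#' @param sample_rate Samples per second (block size).
#' @return Mean proximity in cm.
#' @export
gallagher_index <- function(x, y, goal, sample_rate = 10) {
  n <- length(x)
  if (n == 0) stop("Empty trajectory.", call. = FALSE)
  d <- sqrt((x - goal[1])^2 + (y - goal[2])^2)
  block <- (seq_len(n) - 1) %/% sample_rate
  mean(tapply(d, block, mean))
}

#' Whishaw corridor index
#'
#' Percentage of the swim path lying inside the straight corridor of
#' half-width `corridor_half_width` connecting the release point to the
#' goal. A path segment counts as inside when both of its endpoints are
#' within the corridor (a capsule around the start-goal segment).
#'
#' @param x,y Numeric position vectors (cm), in order.
#' @param start Release point `(x, y)` in cm.
#' @param goal Goal `(x, y)` in cm; must differ from `start`.
#' @param corridor_half_width Corridor half-width in cm.
#' @return Percentage in `[0, 100]`.
#' @export
whishaw_index <- function(x, y, start, goal, corridor_half_width) {
  if (sum((goal - start)^2) < 1e-12) {
    stop("`start` and `goal` must differ.", call. = FALSE)
  }
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  total <- sum(steps)
  if (total <= 0) stop("Zero total path length.", call. = FALSE)
  inside <- dist_to_segment(x, y, start, goal) <= corridor_half_width
  both_in <- inside[-length(inside)] & inside[-1]
  100 * sum(steps[both_in]) / total
}

# Distance from points to the segment a--b.
dist_to_segment <- function(x, y, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  tt <- ((x - a[1]) * abx + (y - a[2]) * aby) / len2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((x - (a[1] + tt * abx))^2 + (y - (a[2] + tt * aby))^2)
}

#' Thigmotaxis (peripheral swimming)
#'
#' Percentage of samples whose radial coordinate falls in the peripheral
#' band of width `band_width` along the pool wall.
#'
#' @param x,y Numeric position vectors (cm), in order.
#' @param pool_radius Pool radius in cm.
#' @param band_width Width of the peripheral band in cm.
#' @return Percentage in `[0, 100]`.
#' @export
thigmotaxis_index <- function(x, y, pool_radius, band_width) {
  if (length(x) == 0) stop("Empty trajectory.", call. = FALSE)
  r <- sqrt(x^2 + y^2)
  100 * mean(r >= pool_radius - band_width)
}

#' Quadrant occupancy
#'
#' Share of samples spent in each pool quadrant; the four percentages sum
#' to 100 exactly (axis ties are resolved deterministically, see
#' [point_quadrant()]).
#'
#' @param x,y Numeric position vectors (cm), in order.
#' @return A named numeric vector (`NE`, `NW`, `SW`, `SE`) of percentages.
#' @export
quadrant_occupancy <- function(x, y) {
  if (length(x) == 0) stop("Empty trajectory.", call. = FALSE)
  q <- factor(point_quadrant(x, y), levels = c("NE", "NW", "SW", "SE"))
  out <- 100 * as.vector(table(q)) / length(x)
  names(out) <- c("NE", "NW", "SW", "SE")
  out
}

#' Per-trial behavioral metrics from tracking records
#'
#' Computes the seven behavioral variables for every trial in a long
#' tracking table (as produced by [simulate_cohort()] or [read_tracking()]).
#' The goal used for latency, Gallagher and Whishaw indices and for the
#' target quadrant depends on the phase: the acquisition platform for
#' pretraining/acquisition/cued trials (pretraining additionally accepts
#' the pool-center platform), its point reflection for reversal trials, and
#' the former platform location for probe trials (which are always censored
#' at the full cutoff and have no escape event).
#'
#' @param tracking A tibble with columns `subject_id`, `group`, `phase`,
#'   `session`, `trial`, `start_point`, `t`, `x`, `y` (plus any additional
#'   identifier columns, which are carried through).
#' @param geometry An [mwm_geometry()].
#' @return A tibble with one row per subject-phase-session-trial carrying
#'   the identifier columns, the seven metric columns (see
#'   [mwm_metric_vars]) and `censored`.
#' @export
trial_metrics <- function(tracking, geometry = mwm_geometry()) {
  needed <- c("subject_id", "group", "phase", "session", "trial",
              "start_point", "t", "x", "y")
  missing_cols <- setdiff(needed, names(tracking))
  if (length(missing_cols)) {
    stop("`tracking` is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id_cols <- intersect(
    c("subject_id", "group", "genotype", "treatment", "phase", "session",
      "trial", "start_point"),
    names(tracking)
  )
  rev_center <- reversal_platform(geometry)
  tq <- geometry$target_quadrant
  rq <- opposite_quadrant(tq)

  tracking |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::group_modify(function(df, key) {
      phase <- key$phase
      goal <- switch(phase,
                     pretraining = c(0, 0),
                     reversal = rev_center,
                     geometry$platform_center)
      quad <- switch(phase, reversal = rq, tq)
      start_xy <- start_position(key$start_point, geometry$pool_radius)
      if (phase == "probe") {
        lat <- list(latency = df$t[length(df$t)], censored = TRUE)
      } else {
        lat <- trial_latency(df$t, df$x, df$y, goal, geometry$platform_radius)
      }
      dist <- path_length(df$x, df$y)
      occ <- quadrant_occupancy(df$x, df$y)
      tibble::tibble(
        latency = lat$latency,
        gallagher = gallagher_index(df$x, df$y, goal,
                                    sample_rate = infer_rate(df$t)),
        whishaw = whishaw_index(df$x, df$y, start_xy, goal,
                                geometry$corridor_half_width),
        thigmotaxis = thigmotaxis_index(df$x, df$y, geometry$pool_radius,
                                        geometry$periphery_band_width),
        quadrant_time = occ[[quad]],
        distance = dist,
        speed = if (lat$latency > 0) dist / lat$latency else 0,
        censored = lat$censored
      )
    }) |>
    dplyr::ungroup()
}

# Samples per second from the time stamps (1 s Gallagher blocks).
infer_rate <- function(t) {
  if (length(t) < 2) return(10L)
  max(1L, as.integer(round(1 / stats::median(diff(t)))))
}

#' Session means of trial metrics
#'
#' Averages the trials of each subject-session into a single record per
#' subject and session (the unit of all downstream analyses). Each metric
#' is the arithmetic mean of its per-trial values; the session counts as
#' censored only when every trial was censored.
#'
#' @param metrics Per-trial metric table from [trial_metrics()] (or a
#'   compatible table with the columns of [mwm_metric_vars] plus
#'   `censored`).
#' @return A tibble with one row per subject-phase-session.
#' @export
session_metrics <- function(metrics) {
  id_cols <- intersect(
    c("subject_id", "group", "genotype", "treatment", "phase", "session"),
    names(metrics)
  )
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(mwm_metric_vars), mean),
      censored = all(.data$censored),
      .groups = "drop"
    )
}

#' Subjects excluded by the cued (visible platform) session
#'
#' The cued session controls for visual and motivational deficits: subjects
#' must reach the visible platform in under 30 s. Subjects with a cued
#' latency of 30 s or more (including censored trials) are flagged for
#' removal from all analyses.
#'
#' @param metrics Per-trial or per-session metric table containing cued
#'   phase rows.
#' @param cutoff Exclusion threshold in seconds.
#' @return Character vector of `subject_id`s to exclude (possibly empty).
#' @export
cued_exclusions <- function(metrics, cutoff = 30) {
  cued <- dplyr::filter(metrics, .data$phase == "cued")
  unique(cued$subject_id[cued$latency >= cutoff])
}
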