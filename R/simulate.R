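#' Simulate a single swim trial
#'
#' Generates one trajectory from a discrete-time heading-persistence random
#' walk. At every 0.1 s step the new heading is the direction of a weighted
#' vector mixture of (i) the bearing to the goal, weighted by the
#' session-dependent goal bias, (ii) a wall-following direction, weighted by
#' the thigmotaxis weight, and (iii) the previous heading (the remainder),
#' plus Gaussian heading noise. Steps that would leave the pool are clamped
#' radially back onto the boundary. The trial ends on platform contact or at
#' the cutoff, in which case the latency is right-censored.
#'
#' The goal-directed component aims at a *remembered* platform location
#' rather than the platform itself: a point drawn around the true center
#' with standard deviation `believed_goal_sd` and redrawn every
#' `belief_refresh` seconds, producing the search bouts of a partially
#' trained animal. With `believed_goal_sd = 0` (the default, and the
#' fully-trained limit) the goal component points exactly at the platform.
#'
#' The simulator draws from R's current random number stream; callers that
#' need reproducibility set the seed beforehand ([simulate_cohort()] manages
#' per-subject substreams itself).
#'
#' @param geometry An [mwm_geometry()].
#' @param goal_bias Weight in `[0, 1]` of the goal-directed component.
#' @param thigmotaxis_weight Weight in `[0, 1]` of the wall-following
#'   component; `goal_bias + thigmotaxis_weight` must not exceed 1.
#' @param speed Swim speed in cm/s (constant within the trial).
#' @param start Release point, one of `"N"`, `"S"`, `"E"`, `"W"`.
#' @param platform_center Platform position `(x, y)` in cm, or `NULL` for a
#'   trial with no goal attraction at all.
#' @param platform_contact If `FALSE` the platform is treated as removed
#'   (probe trials): the goal still attracts the swim but cannot be
#'   contacted, so the trial always runs the full cutoff and is censored.
#' @param heading_sd Per-step heading noise SD in radians.
#' @param believed_goal_sd SD (cm) of the remembered platform location
#'   around the true one; 0 means perfect knowledge.
#' @param belief_refresh Seconds between re-draws of the remembered
#'   location.
#' @param trial_cutoff Cutoff in seconds.
#' @param sample_rate Sampling rate in Hz.
#'
#' @return A tibble with columns `t`, `x`, `y` (one row per sample, sample
#'   `k` at time `k / sample_rate`) and attributes `censored` (logical) and
#'   `start_xy`.
#' @export
#' @examples
#' set.seed(1)
#' traj <- simulate_trial(mwm_geometry(), goal_bias = 0.8,
#'                        thigmotaxis_weight = 0, speed = 20)
#' attr(traj, "censored")
simulate_trial <- function(geometry,
                           goal_bias,
                           thigmotaxis_weight,
                           speed,
                           start = c("N", "S", "E", "W"),
                           platform_center = geometry$platform_center,
                           platform_contact = TRUE,
                           heading_sd = 0.35,
                           believed_goal_sd = 0,
                           belief_refresh = 8,
                           trial_cutoff = 60,
                           sample_rate = 10) {
  start <- match.arg(start)
  if (speed <= 0) stop("`speed` must be positive.", call. = FALSE)
  if (goal_bias < 0 || goal_bias > 1 || thigmotaxis_weight < 0 ||
      thigmotaxis_weight > 1 || goal_bias + thigmotaxis_weight > 1) {
    stop("`goal_bias` and `thigmotaxis_weight` must be in [0, 1] and sum to at most 1.",
         call. = FALSE)
  }
  R <- geometry$pool_radius
  start_xy <- start_position(start, R)
  n_max <- as.integer(round(trial_cutoff * sample_rate))
  dt <- 1 / sample_rate
  step_len <- speed * dt
  has_goal <- !is.null(platform_center)
  can_contact <- has_goal && platform_contact
  if (has_goal) {
    px <- platform_center[1]; py <- platform_center[2]
    pr2 <- geometry$platform_radius^2
  }
  w_goal <- if (has_goal) goal_bias else 0
  w_wall <- thigmotaxis_weight
  w_keep <- 1 - w_goal - w_wall
  # radius below which the wall-following component points outward instead
  # of along the tangent
  r_wall <- R - geometry$periphery_band_width

  noise <- if (heading_sd > 0) stats::rnorm(n_max, 0, heading_sd) else numeric(n_max)
  refresh_every <- max(1L, as.integer(round(belief_refresh * sample_rate)))
  draw_belief <- function() {
    if (!has_goal || believed_goal_sd <= 0) {
      if (has_goal) c(px, py) else c(0, 0)
    } else {
      b <- c(px, py) + stats::rnorm(2, 0, believed_goal_sd)
      rb <- sqrt(sum(b^2))
      if (rb > 0.95 * R) b <- b * 0.95 * R / rb
      b
    }
  }
  belief <- draw_belief()
  xs <- numeric(n_max); ys <- numeric(n_max)
  cx <- start_xy[1]; cy <- start_xy[2]
  heading <- atan2(-cy, -cx)   # initially facing the pool center
  censored <- TRUE
  n_used <- n_max
  for (k in seq_len(n_max)) {
    if (k %% refresh_every == 0L) belief <- draw_belief()
    vx <- w_keep * cos(heading); vy <- w_keep * sin(heading)
    if (w_goal > 0) {
      gx <- belief[1] - cx; gy <- belief[2] - cy
      gn <- sqrt(gx * gx + gy * gy)
      if (gn > 1e-12) { vx <- vx + w_goal * gx / gn; vy <- vy + w_goal * gy / gn }
    }
    if (w_wall > 0) {
      r <- sqrt(cx * cx + cy * cy)
      if (r < r_wall && r > 1e-12) {
        # head for the wall
        vx <- vx + w_wall * cx / r; vy <- vy + w_wall * cy / r
      } else if (r > 1e-12) {
        # follow the tangent that best matches the current heading
        tx <- -cy / r; ty <- cx / r
        if (tx * cos(heading) + ty * sin(heading) < 0) { tx <- -tx; ty <- -ty }
        vx <- vx + w_wall * tx; vy <- vy + w_wall * ty
      }
    }
    if (abs(vx) + abs(vy) > 1e-12) heading <- atan2(vy, vx)
    heading <- heading + noise[k]
    cx <- cx + step_len * cos(heading)
    cy <- cy + step_len * sin(heading)
    r <- sqrt(cx * cx + cy * cy)
    if (r > R) { cx <- cx * R / r; cy <- cy * R / r }
    xs[k] <- cx; ys[k] <- cy
    if (can_contact && (cx - px)^2 + (cy - py)^2 <= pr2) {
      censored <- FALSE
      n_used <- k
      break
    }
    # reached the remembered spot, found nothing: search somewhere else
    if (has_goal && believed_goal_sd > 0 &&
        (cx - belief[1])^2 + (cy - belief[2])^2 <= pr2) {
      belief <- draw_belief()
    }
  }
  out <- tibble::tibble(
    t = seq_len(n_used) * dt,
    x = xs[seq_len(n_used)],
    y = ys[seq_len(n_used)]
  )
  attr(out, "censored") <- censored
  attr(out, "start_xy") <- start_xy
  out
}

# Release positions sit just inside the wall on the main axes.
start_position <- function(start, pool_radius) {
  r <- 0.99 * pool_radius
  switch(start,
         N = c(0, r), S = c(0, -r), E = c(r, 0), W = c(-r, 0))
}

#' Simulate a full cohort of swim trajectories
#'
#' Runs the complete protocol for every subject of a design: one
#' pretraining trial (visible platform at the pool center), the acquisition
#' sessions, a 60 s probe with the platform removed, a cued trial (high
#' goal bias for every group), and the reversal sessions with the platform
#' reflected through the pool center. Within each acquisition or reversal
#' session the four release points N, S, E, W are used in a random
#' permutation.
#'
#' Each subject draws from its own random substream derived from
#' `design$seed` and a stable (group, subject) counter, so the output is
#' bit-identical under the same seed and unaffected for subject A by a
#' change in another group's size.
#'
#' @param design An [mwm_design()].
#' @param geometry An [mwm_geometry()].
#' @param phases Character subset of
#'   `c("pretraining", "acquisition", "probe", "cued", "reversal")` to
#'   simulate (all by default).
#'
#' @return A tibble in long "tracking" format: `subject_id`, `group`,
#'   `genotype`, `treatment`, `phase`, `session`, `trial`, `start_point`,
#'   `censored`, `t`, `x`, `y` — one row per 0.1 s position sample.
#' @export
#' @examples
#' d <- mwm_design(groups = mwm_default_groups(n = rep(2, 8)), seed = 7)
#' trk <- simulate_cohort(d, mwm_geometry(), phases = "acquisition")
#' dplyr::n_distinct(trk$subject_id)
simulate_cohort <- function(design, geometry = mwm_geometry(),
                            phases = c("pretraining", "acquisition", "probe",
                                       "cued", "reversal")) {
  stopifnot(inherits(design, "mwm_design"), inherits(geometry, "mwm_geometry"))
  phases <- match.arg(phases, several.ok = TRUE)
  grs <- design$groups
  rev_center <- reversal_platform(geometry)
  pre_geom_center <- c(0, 0)
  starts_all <- c("N", "S", "E", "W")

  one_subject <- function(gi, si) {
    g <- grs[gi, ]
    sid <- sprintf("%s_%02d", g$group, si)
    set.seed(subject_seed(design$seed, gi, si))
    rows <- list()
    add <- function(traj, phase, session, trial, start) {
      tibble::tibble(
        subject_id = sid, group = g$group, genotype = g$genotype,
        treatment = g$treatment, phase = phase, session = session,
        trial = trial, start_point = start,
        censored = attr(traj, "censored"),
        t = traj$t, x = traj$x, y = traj$y
      )
    }
    sim <- function(bias, thig, platform, start, belief_sd = NULL) {
      speed <- max(2, stats::rnorm(1, g$base_speed, g$speed_sd))
      if (is.null(belief_sd)) {
        belief_sd <- design$belief_error_scale * (1 - bias) *
          geometry$pool_radius
      }
      simulate_trial(geometry, goal_bias = bias, thigmotaxis_weight = thig,
                     speed = speed, start = start, platform_center = platform,
                     heading_sd = design$heading_sd,
                     believed_goal_sd = belief_sd,
                     trial_cutoff = design$trial_cutoff,
                     sample_rate = design$sample_rate)
    }
    if ("pretraining" %in% phases) {
      st <- sample(starts_all, 1)
      rows[[length(rows) + 1]] <-
        add(sim(0.75, min(g$thigmotaxis_weight, 0.25), pre_geom_center, st,
                belief_sd = 0),
            "pretraining", 1L, 1L, st)
    }
    if ("acquisition" %in% phases) {
      for (s in seq_len(design$n_sessions)) {
        bias <- session_goal_bias(g$initial_goal_bias, g$learning_rate, s,
                                  design$max_goal_bias)
        sts <- session_starts(starts_all, design$trials_per_session)
        for (tr in seq_len(design$trials_per_session)) {
          rows[[length(rows) + 1]] <-
            add(sim(bias, g$thigmotaxis_weight, geometry$platform_center, sts[tr]),
                "acquisition", s, tr, sts[tr])
        }
      }
    }
    if ("probe" %in% phases) {
      bias <- session_goal_bias(g$initial_goal_bias, g$learning_rate,
                                design$n_sessions, design$max_goal_bias)
      st <- sample(starts_all, 1)
      # platform removed: the learned bias still points at the old location
      traj <- {
        speed <- max(2, stats::rnorm(1, g$base_speed, g$speed_sd))
        simulate_trial(geometry, goal_bias = bias,
                       thigmotaxis_weight = g$thigmotaxis_weight,
                       speed = speed, start = st,
                       platform_center = geometry$platform_center,
                       platform_contact = FALSE,
                       heading_sd = design$heading_sd,
                       believed_goal_sd = design$belief_error_scale *
                         (1 - bias) * geometry$pool_radius,
                       trial_cutoff = design$trial_cutoff,
                       sample_rate = design$sample_rate)
      }
      rows[[length(rows) + 1]] <- add(traj, "probe", 1L, 1L, st)
    }
    if ("cued" %in% phases) {
      st <- sample(starts_all, 1)
      rows[[length(rows) + 1]] <-
        add(sim(g$cued_goal_bias, min(g$thigmotaxis_weight, 0.1),
                geometry$platform_center, st, belief_sd = 0),
            "cued", 1L, 1L, st)
    }
    if ("reversal" %in% phases && design$n_reversal_sessions > 0) {
      for (s in seq_len(design$n_reversal_sessions)) {
        bias <- session_goal_bias(g$initial_goal_bias, g$learning_rate, s,
                                  design$max_goal_bias)
        sts <- session_starts(starts_all, design$trials_per_session)
        for (tr in seq_len(design$trials_per_session)) {
          rows[[length(rows) + 1]] <-
            add(sim(bias, g$thigmotaxis_weight, rev_center, sts[tr]),
                "reversal", s, tr, sts[tr])
        }
      }
    }
    dplyr::bind_rows(rows)
  }

  out <- purrr::map(seq_len(nrow(grs)), function(gi) {
    purrr::map(seq_len(grs$n[gi]), function(si) one_subject(gi, si)) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
  attr(out, "rng_scheme") <- "per-subject seeds: (master * 2654435761 + 97561*g + 1009*i) mod 2^31-1"
  out
}

# A random permutation of the release points, recycled if a session has
# more trials than release points.
session_starts <- function(starts, n_trials) {
  rep(sample(starts), length.out = n_trials)
}
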