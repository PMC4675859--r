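#' Default experimental groups for a trisomy x treatment cohort
#'
#' Returns the behavioral parameter table for the eight groups of a
#' 2-genotype (WT, TS) by 4-treatment (NT, EE, EGCG, EE-EGCG) design, with
#' the published group sizes (10, 11, 14, 11, 11, 9, 12, 8; 86 subjects in
#' total). The behavioral parameters encode the qualitative structure the
#' downstream analyses assume:
#'
#' * wild-type groups learn fastest; combined EE-EGCG and EE partially
#'   restore learning in trisomic animals; untreated and EGCG-only trisomic
#'   groups learn poorly (WT > TS-EE-EGCG ~ TS-EE > TS ~ TS-EGCG);
#' * trisomic-like groups carry an elevated thigmotactic (wall-hugging)
#'   bias, reduced by enrichment;
#' * EGCG lowers baseline (off-target) swim speed in both genotypes.
#'
#' @param n Optional integer vector of length 8 overriding the group sizes
#'   (order WT-NT, TS-NT, WT-EE, TS-EE, WT-EGCG, TS-EGCG, WT-EE-EGCG,
#'   TS-EE-EGCG).
#' @return A tibble with one row per group: `group`, `genotype`,
#'   `treatment`, `n`, `initial_goal_bias`, `learning_rate`,
#'   `thigmotaxis_weight`, `base_speed`, `speed_sd`, `cued_goal_bias`.
#' @export
mwm_default_groups <- function(n = c(10, 11, 14, 11, 11, 9, 12, 8)) {
  stopifnot(length(n) == 8, all(n >= 1))
  tibble::tibble(
    genotype  = rep(c("WT", "TS"), 4),
    treatment = rep(c("NT", "EE", "EGCG", "EE-EGCG"), each = 2),
    n = as.integer(n),
    initial_goal_bias  = c(0.30, 0.18, 0.30, 0.20, 0.30, 0.18, 0.30, 0.20),
    learning_rate      = c(0.13, 0.020, 0.13, 0.090, 0.13, 0.025, 0.13, 0.100),
    thigmotaxis_weight = c(0.08, 0.35, 0.05, 0.22, 0.08, 0.35, 0.05, 0.20),
    base_speed         = c(22, 22, 22, 22, 18, 18, 19, 19),
    speed_sd           = 3,
    cued_goal_bias     = 0.9
  ) |>
    dplyr::mutate(group = paste(.data$genotype, .data$treatment, sep = "-"),
                  .before = 1)
}

#' Cohort design for a water maze experiment
#'
#' Bundles the group table, the session/trial schedule and the sampling
#' parameters that define a simulated (or real) cohort. The default schedule
#' is the standard protocol: one pretraining trial, five acquisition
#' sessions of four trials each, a 60 s probe (platform removed), a cued
#' session, and three reversal sessions of four trials with the platform
#' moved to the opposite quadrant. Trials are cut off at 60 s and positions
#' sampled at 10 Hz.
#'
#' @param groups Group parameter table as returned by
#'   [mwm_default_groups()]; must contain columns `group`, `genotype`,
#'   `treatment`, `n`, `initial_goal_bias`, `learning_rate`,
#'   `thigmotaxis_weight`, `base_speed`, `speed_sd`, and optionally
#'   `cued_goal_bias`.
#' @param n_sessions Number of acquisition sessions.
#' @param trials_per_session Trials per acquisition/reversal session.
#' @param n_reversal_sessions Number of reversal sessions.
#' @param trial_cutoff Trial cutoff in seconds; latencies are
#'   right-censored here.
#' @param sample_rate Position sampling rate in Hz. `trial_cutoff *
#'   sample_rate` must be a whole number of samples.
#' @param heading_sd Step-to-step heading noise (radians) of the simulated
#'   swim policy.
#' @param max_goal_bias Upper cap on the session-dependent goal bias.
#' @param belief_error_scale Spatial-memory error of the simulated animals,
#'   as a fraction of the pool radius: the remembered platform location is
#'   drawn with SD `belief_error_scale * (1 - goal_bias) * pool_radius`, so
#'   it shrinks to zero as a group learns.
#' @param seed Master seed; per-subject substreams are derived from it so
#'   that changing one group's size does not perturb other subjects' draws.
#'
#' @return An object of class `mwm_design`.
#' @export
#' @examples
#' design <- mwm_design()
#' sum(design$groups$n)  # 86 subjects
mwm_design <- function(groups = mwm_default_groups(),
                       n_sessions = 5,
                       trials_per_session = 4,
                       n_reversal_sessions = 3,
                       trial_cutoff = 60,
                       sample_rate = 10,
                       heading_sd = 0.35,
                       max_goal_bias = 0.92,
                       belief_error_scale = 0.6,
                       seed = 1L) {
  groups <- tibble::as_tibble(groups)
  needed <- c("group", "genotype", "treatment", "n", "initial_goal_bias",
              "learning_rate", "thigmotaxis_weight", "base_speed", "speed_sd")
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols)) {
    stop("`groups` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"cued_goal_bias" %in% names(groups)) groups$cued_goal_bias <- 0.9
  if (anyDuplicated(groups$group)) stop("Group labels must be unique.", call. = FALSE)
  if (any(groups$n < 1)) stop("All group sizes must be >= 1.", call. = FALSE)
  with(groups, {
    if (any(initial_goal_bias < 0 | initial_goal_bias > 1)) {
      stop("`initial_goal_bias` must be in [0, 1].", call. = FALSE)
    }
    if (any(learning_rate < 0)) stop("`learning_rate` must be >= 0.", call. = FALSE)
    if (any(thigmotaxis_weight < 0 | thigmotaxis_weight > 1)) {
      stop("`thigmotaxis_weight` must be in [0, 1].", call. = FALSE)
    }
    if (any(initial_goal_bias + thigmotaxis_weight > 1)) {
      stop("`initial_goal_bias + thigmotaxis_weight` must not exceed 1.",
           call. = FALSE)
    }
    if (any(base_speed <= 0)) stop("`base_speed` must be positive.", call. = FALSE)
  })
  n_samples <- trial_cutoff * sample_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("`trial_cutoff * sample_rate` must be an integer sample count.",
         call. = FALSE)
  }
  stopifnot(n_sessions >= 1, trials_per_session >= 1, n_reversal_sessions >= 0,
            trial_cutoff > 0, sample_rate > 0, heading_sd >= 0,
            belief_error_scale >= 0)
  structure(
    list(
      groups = groups,
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      n_reversal_sessions = as.integer(n_reversal_sessions),
      trial_cutoff = trial_cutoff,
      sample_rate = sample_rate,
      heading_sd = heading_sd,
      max_goal_bias = max_goal_bias,
      belief_error_scale = belief_error_scale,
      seed = as.integer(seed)
    ),
    class = "mwm_design"
  )
}

#' @export
print.mwm_design <- function(x, ...) {
  cat("<mwm_design>\n")
  cat(sprintf("  %d groups, %d subjects\n", nrow(x$groups), sum(x$groups$n)))
  cat(sprintf("  %d acquisition sessions x %d trials, %d reversal sessions\n",
              x$n_sessions, x$trials_per_session, x$n_reversal_sessions))
  cat(sprintf("  cutoff %.0f s at %.0f Hz, seed %d\n",
              x$trial_cutoff, x$sample_rate, x$seed))
  invisible(x)
}

# Session-dependent goal bias for one group (learning curve).
session_goal_bias <- function(initial, rate, session, cap = 0.92) {
  pmin(initial + rate * (session - 1), cap)
}

# Deterministic per-subject seed derived from the master seed and a stable
# (group index, within-group index) counter, so adding subjects to one group
# leaves all other subjects' streams untouched.
subject_seed <- function(master_seed, group_index, subject_index) {
  as.integer((as.double(master_seed) * 2654435761 +
                group_index * 97561 + subject_index * 1009) %% 2147483647)
}
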