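#' Expected metric trajectories implied by a cohort design
#'
#' Translates each group's behavioral parameters (goal bias, learning
#' rate, thigmotaxis weight, swim speed) into per-session expected values
#' of the seven behavioral variables, together with a between-subject
#' covariance. This is the "effect specification" consumed by
#' [simulate_metric_table()], the fast statistical stand-in for full
#' trajectory simulation.
#'
#' @param design An [mwm_design()].
#' @param covariance Optional 7x7 covariance matrix of subject-session
#'   deviations (rows/columns in [mwm_metric_vars] order); the default is
#'   diagonal with realistic per-metric spreads.
#' @return A list with `means` (tibble: `group`, `session`, one column per
#'   metric) and `covariance`.
#' @export
default_effect_spec <- function(design, covariance = NULL) {
  stopifnot(inherits(design, "mwm_design"))
  if (is.null(covariance)) {
    sds <- c(latency = 8, gallagher = 5, whishaw = 8, thigmotaxis = 7,
             quadrant_time = 8, distance = 120, speed = 2.5)
    covariance <- diag(sds[mwm_metric_vars]^2)
    dimnames(covariance) <- list(mwm_metric_vars, mwm_metric_vars)
  }
  cutoff <- design$trial_cutoff
  means <- tidyr::expand_grid(
    design$groups[, c("group", "initial_goal_bias", "learning_rate",
                      "thigmotaxis_weight", "base_speed")],
    session = seq_len(design$n_sessions)
  ) |>
    dplyr::mutate(
      bias = session_goal_bias(.data$initial_goal_bias, .data$learning_rate,
                               .data$session, design$max_goal_bias),
      latency = pmin(cutoff, 6 + (cutoff - 10) * (1 - .data$bias)^1.5),
      gallagher = 12 + 40 * (1 - .data$bias),
      whishaw = 5 + 80 * .data$bias,
      thigmotaxis = pmin(95, 15 * (1 - .data$bias) +
                           70 * .data$thigmotaxis_weight),
      quadrant_time = 20 + 40 * .data$bias,
      distance = .data$base_speed * .data$latency * 0.95,
      speed = .data$base_speed
    ) |>
    dplyr::select("group", "session", dplyr::all_of(mwm_metric_vars))
  list(means = means, covariance = covariance)
}

#' Simulate a per-subject-session metric table directly
#'
#' Draws subject-session metric records from a multivariate normal around
#' the group-session mean vectors of an effect specification, truncating
#' each variable to its valid range (percentages to `[0, 100]`, latency to
#' `(0, cutoff]`, lengths and speeds to non-negative values). Latencies at
#' the cutoff are flagged censored. This bypasses trajectory simulation
#' entirely and is the fast path for statistical testing: everything
#' downstream of [session_metrics()] is a pure function of this table.
#'
#' @param design An [mwm_design()].
#' @param effect_spec A list with `means` and `covariance` as returned by
#'   [default_effect_spec()].
#' @param seed Integer seed (defaults to the design's).
#' @return A tibble shaped like [session_metrics()] output: `subject_id`,
#'   `group`, `genotype`, `treatment`, `phase = "acquisition"`, `session`,
#'   the seven metric columns, `censored`.
#' @export
simulate_metric_table <- function(design,
                                  effect_spec = default_effect_spec(design),
                                  seed = design$seed) {
  stopifnot(inherits(design, "mwm_design"))
  Sigma <- as.matrix(effect_spec$covariance)
  if (nrow(Sigma) != length(mwm_metric_vars) ||
      ncol(Sigma) != length(mwm_metric_vars)) {
    stop("`covariance` must be 7 x 7 in mwm_metric_vars order.", call. = FALSE)
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("`covariance` is not positive semi-definite.", call. = FALSE)
  }
  means <- effect_spec$means
  bad_pct <- means |>
    dplyr::filter(dplyr::if_any(c("whishaw", "thigmotaxis", "quadrant_time"),
                                ~ .x < 0 | .x > 100))
  if (nrow(bad_pct)) {
    stop("Percentage means must lie in [0, 100].", call. = FALSE)
  }
  if (any(means$latency <= 0 | means$latency > design$trial_cutoff)) {
    stop("Latency means must lie in (0, cutoff].", call. = FALSE)
  }
  cutoff <- design$trial_cutoff
  grs <- design$groups
  nv <- length(mwm_metric_vars)
  # one factor of the covariance for the whole cohort (handles the
  # semi-definite case, unlike a plain Cholesky)
  ed <- eigen(Sigma, symmetric = TRUE)
  A <- t(ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors)))
  clamp <- function(M) {
    M[, 1] <- pmin(pmax(M[, 1], 0.1), cutoff)      # latency
    M[, 2] <- pmax(M[, 2], 0)                      # gallagher
    for (j in 3:5) M[, j] <- pmin(pmax(M[, j], 0), 100)  # percentages
    M[, 6] <- pmax(M[, 6], 0)                      # distance
    M[, 7] <- pmax(M[, 7], 0.1)                    # speed
    M
  }
  out <- purrr::map(seq_len(nrow(grs)), function(gi) {
    g <- grs[gi, ]
    mu_s <- dplyr::filter(means, .data$group == g$group) |>
      dplyr::arrange(.data$session)
    mu_mat <- as.matrix(mu_s[, mwm_metric_vars])
    S <- nrow(mu_s)
    rows <- lapply(seq_len(g$n), function(si) {
      set.seed(subject_seed(seed, gi, si))
      clamp(matrix(stats::rnorm(S * nv), S, nv) %*% A + mu_mat)
    })
    M <- do.call(rbind, rows)
    colnames(M) <- mwm_metric_vars
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = rep(sprintf("%s_%02d", g$group, seq_len(g$n)), each = S),
        group = g$group, genotype = g$genotype, treatment = g$treatment,
        phase = "acquisition", session = rep(mu_s$session, g$n)
      ),
      tibble::as_tibble(M)
    ) |>
      dplyr::mutate(censored = .data$latency >= cutoff)
  }) |> dplyr::bind_rows()
  out
}
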