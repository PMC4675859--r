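#' Variance decomposition of the ordination
#'
#' Decomposes the variance of the supervised ordination into its
#' between-group, between-session and within-session parts. All variances
#' use the same formula `V = 1/(v N) * sum(d_i^2)` with `v` the number of
#' variables and `d_i` the distance of object `i` from the origin of the
#' full-rank scores:
#'
#' * `V_B` (between-group): objects are the `N = G x S` median-table rows.
#'   Because the PCA is fitted to those rows with population scaling,
#'   `V_B = 1` by construction.
#' * `V_T` (total): objects are the individual supplementary points
#'   (`N = subjects x sessions`).
#' * `V_BS` (between-session): objects are the `S` per-session averages of
#'   the `G` group score vectors, `d_s^2 = sum_p (mean_j x_{s,p,j})^2`.
#' * `V_WS` (within-session): the difference `V_B - V_BS`, the average
#'   separation of the groups within a session.
#'
#' Percentages are expressed against `V_T`; the within-group percentage is
#' `100 - V_B / V_T * 100`.
#'
#' @param model An [mwm_pca()] fit with `group`/`session` labels.
#' @param supplementary Individual coordinates from
#'   [project_supplementary()]; must contain a `session` column covering
#'   exactly the model's sessions.
#' @return An object of class `mwm_vardecomp`: list with `v_total`,
#'   `v_between`, `v_between_session`, `v_within_session`, the derived
#'   percentages `pct_between`, `pct_within_group`, `pct_between_session`,
#'   `pct_within_session`, and the problem sizes.
#' @export
decompose_variance <- function(model, supplementary) {
  stopifnot(inherits(model, "mwm_pca"))
  pcs <- colnames(model$loadings)
  if (!all(pcs %in% names(supplementary))) {
    stop("`supplementary` lacks the model's score columns.", call. = FALSE)
  }
  if (!"session" %in% names(supplementary) ||
      !"session" %in% names(model$scores)) {
    stop("Both model scores and supplementary points need a `session` column.",
         call. = FALSE)
  }
  mod_sessions <- sort(unique(model$scores$session))
  sup_sessions <- sort(unique(supplementary$session))
  if (!identical(mod_sessions, sup_sessions)) {
    stop("Session labels of model rows and individuals do not match.",
         call. = FALSE)
  }
  n_vars <- length(model$vars)
  S_med <- as.matrix(model$scores[, pcs, drop = FALSE])
  v_between <- sum(S_med^2) / (n_vars * nrow(S_med))
  S_ind <- as.matrix(supplementary[, pcs, drop = FALSE])
  v_total <- sum(S_ind^2) / (n_vars * nrow(S_ind))
  d2_s <- vapply(mod_sessions, function(s) {
    sum(colMeans(S_med[model$scores$session == s, , drop = FALSE])^2)
  }, numeric(1))
  v_between_session <- sum(d2_s) / (n_vars * length(mod_sessions))
  v_within_session <- v_between - v_between_session
  structure(
    list(
      v_total = v_total,
      v_between = v_between,
      v_between_session = v_between_session,
      v_within_session = v_within_session,
      pct_between = 100 * v_between / v_total,
      pct_within_group = 100 - 100 * v_between / v_total,
      pct_between_session = 100 * v_between_session / v_total,
      pct_within_session = 100 * v_within_session / v_total,
      n_vars = n_vars,
      n_groups = length(unique(model$scores$group)),
      n_sessions = length(mod_sessions),
      n_individual_points = nrow(S_ind),
      d2_session = d2_s
    ),
    class = "mwm_vardecomp"
  )
}

#' @export
print.mwm_vardecomp <- function(x, ...) {
  cat("<mwm_vardecomp>\n")
  cat(sprintf("  V_B  = %.4f (%.1f%% of total; within-group %.1f%%)\n",
              x$v_between, x$pct_between, x$pct_within_group))
  cat(sprintf("  V_BS = %.4f (%.1f%%)   V_WS = %.4f (%.1f%%)\n",
              x$v_between_session, x$pct_between_session,
              x$v_within_session, x$pct_within_session))
  invisible(x)
}

#' @describeIn decompose_variance Tidy the decomposition: one row per
#'   component with its variance and percent of total.
#' @param x An `mwm_vardecomp` object.
#' @param ... Unused.
#' @export
tidy.mwm_vardecomp <- function(x, ...) {
  tibble::tibble(
    component = c("total", "between_group", "within_group",
                  "between_session", "within_session"),
    variance = c(x$v_total, x$v_between, x$v_total - x$v_between,
                 x$v_between_session, x$v_within_session),
    pct_of_total = c(100, x$pct_between, x$pct_within_group,
                     x$pct_between_session, x$pct_within_session)
  )
}
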