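#' Group-by-session median table
#'
#' Builds the supervised-PCA input: for every (group, session) cell, the
#' median over subjects of the subject's session-mean metrics. Medians
#' (midpoint of the two central order statistics for even counts) are used
#' instead of means for robustness to outlying subjects. With eight groups
#' and five acquisition sessions this is the 40-observation table the
#' ordination is fitted to.
#'
#' @param session_metrics Per-subject-session table from
#'   [session_metrics()]; only rows of one phase should be passed.
#' @param vars Metric columns to include.
#' @return A tibble with columns `group`, `session`, and one column per
#'   metric; `G x S` rows ordered by group then session.
#' @export
#' @examples
#' # three subjects, one group/session: median is robust to the outlier
#' sm <- tibble::tibble(subject_id = c("a", "b", "c"), group = "g1",
#'                      session = 1, latency = c(1, 2, 100))
#' group_median_table(sm, vars = "latency")$latency  # 2
group_median_table <- function(session_metrics, vars = mwm_metric_vars) {
  stopifnot(all(c("group", "session") %in% names(session_metrics)))
  missing_vars <- setdiff(vars, names(session_metrics))
  if (length(missing_vars)) {
    stop("Missing metric columns: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(session_metrics$group)
  sessions <- sort(unique(session_metrics$session))
  full <- tidyr::expand_grid(group = groups, session = sessions)
  have <- dplyr::distinct(session_metrics, .data$group, .data$session)
  empty <- dplyr::anti_join(full, have, by = c("group", "session"))
  if (nrow(empty)) {
    stop("Empty (group, session) cell(s): ",
         paste(sprintf("(%s, %s)", empty$group, empty$session), collapse = ", "),
         call. = FALSE)
  }
  session_metrics |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars), stats::median),
                     .groups = "drop") |>
    dplyr::arrange(.data$group, .data$session)
}

#' Supervised PCA of a group-median table
#'
#' Fits a principal component analysis to the group-by-session median
#' table. Columns are Z-scored with the population (divide-by-N) variance
#' convention, so the sum of the eigenvalues equals the number of variables
#' and the between-group variance of the resulting scores is exactly 1
#' under the variance decomposition of [decompose_variance()]. Row scores
#' are in distance-preserving (principal) coordinates: pairwise Euclidean
#' distances between full-rank scores equal those between the Z-scored
#' rows.
#'
#' Component signs are fixed deterministically: PC1 is oriented so the
#' Gallagher-index loading is negative (high PC1 = proximal search, i.e.
#' better learning), PC2 so the speed loading is positive, and any further
#' component so its largest-magnitude loading is positive.
#'
#' @param median_table Output of [group_median_table()].
#' @param vars Metric columns used as PCA variables.
#' @return An object of class `mwm_pca`: list with `center`, `scale`
#'   (population SDs), `eigenvalues`, `pct_var`, `loadings` (variables x
#'   components, orthonormal), `contributions` (percent per component,
#'   columns sum to 100), `scores` (tibble with `group`, `session`,
#'   `PC1..PCk`), `vars`, `n_obs`.
#' @export
mwm_pca <- function(median_table, vars = mwm_metric_vars) {
  X <- as.matrix(median_table[, vars, drop = FALSE])
  n <- nrow(X)
  if (n < 2) stop("Need at least 2 rows to fit a PCA.", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale_pop <- sqrt(colMeans(Xc^2))
  if (any(scale_pop < 1e-12)) {
    bad <- vars[scale_pop < 1e-12]
    stop("Zero-variance column(s): ", paste(bad, collapse = ", "),
         ". Remove them or add jitter before fitting.", call. = FALSE)
  }
  Z <- sweep(Xc, 2, scale_pop, "/")
  sv <- svd(Z)
  k <- length(vars)
  d <- sv$d
  loadings <- sv$v
  scores <- sv$u %*% diag(d, nrow = length(d))
  # deterministic sign orientation
  for (p in seq_len(ncol(loadings))) {
    flip <- FALSE
    if (p == 1 && "gallagher" %in% vars) {
      flip <- loadings[match("gallagher", vars), 1] > 0
    } else if (p == 2 && "speed" %in% vars) {
      flip <- loadings[match("speed", vars), 2] < 0
    } else {
      j <- which.max(abs(loadings[, p]))
      flip <- loadings[j, p] < 0
    }
    if (flip) {
      loadings[, p] <- -loadings[, p]
      scores[, p] <- -scores[, p]
    }
  }
  eigenvalues <- d^2 / n
  dimnames(loadings) <- list(vars, paste0("PC", seq_along(d)))
  colnames(scores) <- paste0("PC", seq_along(d))
  score_tbl <- dplyr::bind_cols(
    median_table[, intersect(c("group", "session"), names(median_table)),
                 drop = FALSE],
    tibble::as_tibble(scores)
  )
  structure(
    list(
      center = center,
      scale = scale_pop,
      eigenvalues = eigenvalues,
      pct_var = 100 * eigenvalues / sum(eigenvalues),
      loadings = loadings,
      contributions = 100 * loadings^2,
      scores = score_tbl,
      vars = vars,
      n_obs = n
    ),
    class = "mwm_pca"
  )
}

#' @export
print.mwm_pca <- function(x, ...) {
  cat("<mwm_pca> ", x$n_obs, " observations, ", length(x$vars), " variables\n",
      sep = "")
  cat("  % variance: ",
      paste(sprintf("PC%d %.1f", seq_along(x$pct_var), x$pct_var),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project individual records as supplementary points
#'
#' Maps individual subject-session records into an already fitted
#' group-median ordination without altering its axes: each record is
#' centered and scaled by the model's constants (those of the median
#' table) and multiplied through the loadings. Projecting a median-table
#' row returns exactly its fitted score, and the projection is affine in
#' its input.
#'
#' @param session_metrics Table with the model's metric columns plus any
#'   identifier columns (carried through).
#' @param model An [mwm_pca()] fit.
#' @return A tibble: identifier columns followed by `PC1..PCk`.
#' @export
project_supplementary <- function(session_metrics, model) {
  stopifnot(inherits(model, "mwm_pca"))
  missing_vars <- setdiff(model$vars, names(session_metrics))
  if (length(missing_vars)) {
    stop("Missing variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(session_metrics[, model$vars, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  S <- Z %*% model$loadings
  colnames(S) <- colnames(model$loadings)
  id_cols <- setdiff(names(session_metrics), model$vars)
  dplyr::bind_cols(session_metrics[, id_cols, drop = FALSE],
                   tibble::as_tibble(S))
}

#' Per-group session trajectories in the ordination plane
#'
#' Orders each group's median scores by session, giving the learning
#' trajectory of the group through the (PC1, PC2) plane. With the fixed
#' sign convention (see [mwm_pca()]), learning moves groups toward higher
#' PC1.
#'
#' @param model An [mwm_pca()] fit with `group` and `session` score labels.
#' @return A tibble `group`, `session`, `PC1`, `PC2` ordered by group and
#'   session.
#' @export
pc_trajectories <- function(model) {
  stopifnot(inherits(model, "mwm_pca"))
  sc <- model$scores
  if (!all(c("group", "session") %in% names(sc))) {
    stop("Model scores carry no (group, session) labels.", call. = FALSE)
  }
  sc |>
    dplyr::select("group", "session", "PC1", "PC2") |>
    dplyr::arrange(.data$group, .data$session)
}

#' @describeIn mwm_pca Tidy the loadings and contributions: one row per
#'   (variable, component) with `loading` and `contribution` (%).
#' @param x,object An `mwm_pca` object.
#' @param ... Unused.
#' @export
tidy.mwm_pca <- function(x, ...) {
  tibble::tibble(
    variable = rep(rownames(x$loadings), times = ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings),
    contribution = as.vector(x$contributions)
  )
}

#' @describeIn mwm_pca One-row model summary: observations, variables, and
#'   the percent variance of the first two components.
#' @export
glance.mwm_pca <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_vars = length(x$vars),
    pc1_pct_var = x$pct_var[1],
    pc2_pct_var = x$pct_var[2],
    total_variance = sum(x$eigenvalues)
  )
}

#' @describeIn mwm_pca Plot the per-group session trajectories in the
#'   (PC1, PC2) plane.
#' @export
autoplot.mwm_pca <- function(object, ...) {
  tr <- pc_trajectories(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group, group = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::geom_text(ggplot2::aes(label = .data$session), show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pct_var[1]),
      y = sprintf("PC2 (%.1f%%)", object$pct_var[2])
    )
}

#' Variable contribution bar chart of a fitted ordination
#'
#' @param model An [mwm_pca()] fit.
#' @param components Components to display.
#' @return A ggplot object.
#' @export
plot_contributions <- function(model, components = c("PC1", "PC2")) {
  td <- tidy(model) |>
    dplyr::filter(.data$component %in% components)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$variable, y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = NULL, y = "contribution (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
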