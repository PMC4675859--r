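#' Repeated-measures ANOVA with Tukey post-hoc comparisons
#'
#' Tests the overall group (genotype x treatment) effect on one behavioral
#' metric across sessions. The group effect is assessed in the
#' between-subject stratum of `aov(value ~ group + Error(subject_id))`, so
#' with 86 subjects in 8 groups the F statistic has (7, 78) degrees of
#' freedom. Pairwise group differences use Tukey's HSD on the per-subject
#' session-averaged values, with Benjamini-Hochberg adjustment of the
#' Tukey p-values.
#'
#' @param session_metrics Per-subject-session table ([session_metrics()]).
#' @param metric Metric column to analyze.
#' @param phase Optional phase to filter to first.
#' @return An object of class `mwm_anova`: `overall` (one-row tibble with
#'   `term`, `df1`, `df2`, `statistic`, `p_value`) and `posthoc` (tibble
#'   with `contrast`, `estimate`, `conf_low`, `conf_high`, `p_tukey`,
#'   `p_bh`).
#' @export
rm_anova_posthoc <- function(session_metrics, metric, phase = NULL) {
  df <- session_metrics
  if (!is.null(phase)) df <- dplyr::filter(df, .data$phase == !!phase)
  stopifnot(all(c("subject_id", "group", metric) %in% names(df)))
  df <- tibble::tibble(
    subject_id = factor(df$subject_id),
    group = factor(df$group),
    value = df[[metric]]
  )
  sizes <- table(dplyr::distinct(df, .data$subject_id, .data$group)$group)
  if (length(sizes) < 2) stop("Need at least 2 groups.", call. = FALSE)
  if (any(sizes < 2)) {
    stop("Every group needs at least 2 subjects.", call. = FALSE)
  }
  fit <- stats::aov(value ~ group + Error(subject_id), data = df)
  stratum <- summary(fit)[["Error: subject_id"]][[1]]
  rn <- trimws(rownames(stratum))
  gi <- match("group", rn)
  ri <- match("Residuals", rn)
  overall <- tibble::tibble(
    term = "group",
    df1 = stratum[gi, "Df"],
    df2 = stratum[ri, "Df"],
    statistic = stratum[gi, "F value"],
    p_value = stratum[gi, "Pr(>F)"]
  )
  subj_means <- df |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  tuk <- stats::TukeyHSD(stats::aov(value ~ group, data = subj_means))$group
  posthoc <- tibble::tibble(
    contrast = rownames(tuk),
    estimate = tuk[, "diff"],
    conf_low = tuk[, "lwr"],
    conf_high = tuk[, "upr"],
    p_tukey = tuk[, "p adj"],
    p_bh = bh_adjust(tuk[, "p adj"])
  )
  structure(
    list(overall = overall, posthoc = posthoc, metric = metric),
    class = "mwm_anova"
  )
}

#' @export
print.mwm_anova <- function(x, ...) {
  cat("<mwm_anova> ", x$metric, "\n", sep = "")
  cat(sprintf("  group effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$overall$df1, x$overall$df2, x$overall$statistic,
              x$overall$p_value))
  invisible(x)
}

#' @describeIn rm_anova_posthoc Post-hoc comparison table as a tibble.
#' @param x An `mwm_anova` object.
#' @param ... Unused.
#' @export
tidy.mwm_anova <- function(x, ...) x$posthoc

#' @describeIn rm_anova_posthoc Overall test as a one-row tibble.
#' @export
glance.mwm_anova <- function(x, ...) x$overall

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by `m / rank`,
#' enforce monotonicity from the largest down, cap at 1 and restore the
#' input order. Controls the FDR across a family of post-hoc comparisons.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
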