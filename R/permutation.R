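#' Randomly reassign subjects to groups of fixed sizes
#'
#' Draws a uniform random partition of the subjects into groups with the
#' original group sizes. Every subject keeps its full session record under
#' its new label, which is the session-linked relabeling scheme of the
#' permutation tests.
#'
#' @param subject_ids Character vector of distinct subject identifiers.
#' @param group_sizes Named integer vector (names = group labels); must sum
#'   to `length(subject_ids)`.
#' @return A tibble `subject_id`, `group` with the permuted assignment.
#' @export
permute_group_labels <- function(subject_ids, group_sizes) {
  n <- length(subject_ids)
  if (sum(group_sizes) != n) {
    stop("`group_sizes` must sum to the number of subjects.", call. = FALSE)
  }
  if (is.null(names(group_sizes))) {
    stop("`group_sizes` must be named by group label.", call. = FALSE)
  }
  labels <- rep(names(group_sizes), times = group_sizes)
  tibble::tibble(
    subject_id = subject_ids,
    group = labels[sample.int(n)]
  )
}

# ---- internal permutation machinery -------------------------------------
# The tests below re-derive median table -> PCA -> supplementary projection
# -> variance decomposition for the observed labels and for every
# permutation draw, working on plain matrices for speed.

# Split a subject-session matrix into the (group, session) median table.
# Tight loop inside every permutation draw: one radix sort per column keyed
# by (cell, value), then the median is the midpoint of the two central
# order statistics by index arithmetic.
.median_table_matrix <- function(X, cell, n_cells) {
  sizes <- tabulate(cell, n_cells)
  if (any(sizes == 0L)) {
    stop("Empty (group, session) cell in permutation.", call. = FALSE)
  }
  hi <- cumsum(sizes)
  lo <- hi - sizes + 1L
  h1 <- lo + (sizes - 1L) %/% 2L
  h2 <- lo + sizes %/% 2L
  nv <- ncol(X)
  M <- matrix(0, n_cells, nv)
  for (j in seq_len(nv)) {
    y <- X[, j]
    ys <- y[order(cell, y, method = "radix")]
    M[, j] <- (ys[h1] + ys[h2]) / 2
  }
  M
}

# Full pipeline statistics for one group assignment.
# X: subject-session matrix (rows sorted arbitrarily), row_subject: subject
# index per row, row_session_idx: session index per row, g_of_subject:
# group index per subject. Returns within-session % of total variance and,
# if target_session is given, the individual PC1 coordinates at that
# session split by group.
.assignment_stats <- function(X, row_subject, row_session_idx, g_of_subject,
                              n_groups, n_sessions, target_session = NULL,
                              pc1_flip_idx = NULL) {
  g_row <- g_of_subject[row_subject]
  cell <- (g_row - 1L) * n_sessions + row_session_idx
  n_cells <- n_groups * n_sessions
  M <- .median_table_matrix(X, cell, n_cells)
  n_vars <- ncol(X)
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  scl <- sqrt(colMeans(Mc^2))
  scl[scl < 1e-12] <- 1e-12
  Z <- sweep(Mc, 2, scl, "/")
  sv <- svd(Z)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  v_between <- sum(scores^2) / (n_vars * n_cells)
  # per-session average over the group rows (cells ordered g-major)
  sess_of_cell <- rep(seq_len(n_sessions), times = n_groups)
  d2_s <- vapply(seq_len(n_sessions), function(s) {
    sum(colMeans(scores[sess_of_cell == s, , drop = FALSE])^2)
  }, numeric(1))
  v_bs <- sum(d2_s) / (n_vars * n_sessions)
  Z_ind <- sweep(sweep(X, 2, center), 2, scl, "/")
  v_total <- sum(Z_ind^2) / (n_vars * nrow(X))
  out <- list(stat_ws = 100 * (v_between - v_bs) / v_total)
  if (!is.null(target_session)) {
    v1 <- sv$v[, 1]
    # orient PC1 as in mwm_pca (proximity loading negative)
    if (!is.null(pc1_flip_idx) && v1[pc1_flip_idx] > 0) v1 <- -v1
    sel <- row_session_idx == target_session
    pc1 <- (Z_ind %*% v1)[sel]
    out$pc1_by_group <- split(pc1, g_row[sel])
  }
  out
}

# Welch two-sample t statistic.
.welch_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  (mean(x1) - mean(x2)) / sqrt(stats::var(x1) / n1 + stats::var(x2) / n2)
}

# Common setup: session-mean metric table -> matrices.
.perm_setup <- function(session_metrics, vars) {
  stopifnot(all(c("subject_id", "group", "session") %in% names(session_metrics)))
  sm <- dplyr::arrange(session_metrics, .data$subject_id, .data$session)
  subjects <- unique(sm$subject_id)
  sessions <- sort(unique(sm$session))
  groups <- sort(unique(sm$group))
  subj_idx <- match(sm$subject_id, subjects)
  sess_idx <- match(sm$session, sessions)
  g_tab <- dplyr::distinct(sm, .data$subject_id, .data$group)
  if (nrow(g_tab) != length(subjects)) {
    stop("A subject appears under more than one group label.", call. = FALSE)
  }
  g_of_subject <- match(g_tab$group[match(subjects, g_tab$subject_id)], groups)
  list(
    X = as.matrix(sm[, vars, drop = FALSE]),
    row_subject = subj_idx,
    row_session_idx = sess_idx,
    g_of_subject = g_of_subject,
    subjects = subjects,
    sessions = sessions,
    groups = groups
  )
}

#' Permutation test of overall group separation
#'
#' Tests whether the experimental groups are separated in the ordination
#' beyond chance. The statistic is the within-session variance as a
#' percentage of total variance (see [decompose_variance()]): the average
#' separation of the group medians within a session, on the scale of the
#' total individual variance. Under each of the `B` permutations, subjects
#' are randomly reassigned to groups of the original sizes (keeping each
#' subject's sessions together), and the whole pipeline — median table,
#' PCA, supplementary projection, decomposition — is re-derived. The
#' p-value is upper-tail with the add-one convention
#' `(1 + #(null >= observed)) / (1 + B)`, so it is never exactly zero.
#'
#' @param session_metrics Per-subject-session metric table (one phase).
#' @param B Number of permutations.
#' @param vars Metric columns.
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `mwm_permtest`: list with `statistic_kind`,
#'   `observed`, `null` (length `B`), `B`, `p_value`, `seed`.
#' @export
separation_test <- function(session_metrics, B = 10000,
                            vars = mwm_metric_vars, seed = NULL) {
  if (B < 1) stop("`B` must be at least 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- .perm_setup(session_metrics, vars)
  if (length(st$groups) < 2) stop("Need at least 2 groups.", call. = FALSE)
  n_groups <- length(st$groups); n_sessions <- length(st$sessions)
  observed <- .assignment_stats(st$X, st$row_subject, st$row_session_idx,
                                st$g_of_subject, n_groups, n_sessions)$stat_ws
  n_subj <- length(st$subjects)
  null <- vapply(seq_len(B), function(b) {
    g_perm <- st$g_of_subject[sample.int(n_subj)]
    .assignment_stats(st$X, st$row_subject, st$row_session_idx, g_perm,
                      n_groups, n_sessions)$stat_ws
  }, numeric(1))
  structure(
    list(
      statistic_kind = "within_session_separation",
      observed = observed,
      null = null,
      B = B,
      p_value = (1 + sum(null >= observed)) / (1 + B),
      seed = seed
    ),
    class = "mwm_permtest"
  )
}

#' Pairwise permutation tests of learning differences on PC1
#'
#' For a chosen session, compares every pair of groups by a Welch
#' two-sample t statistic on the individual (supplementary) PC1
#' coordinates of their subjects. The null distribution relabels subjects
#' to groups of the original sizes and refits the full PCA pipeline at
#' every draw; all pairs are evaluated on the same permutation stream.
#' Two-sided p-values use the add-one convention. A familywise-adjusted
#' p-value (`p_fw`) against the null distribution of the maximum |t| over
#' all pairs is reported alongside the raw per-pair p-values.
#'
#' @inheritParams separation_test
#' @param session The session (label, as in the data) to compare groups at.
#' @return An object of class `mwm_pairwise_permtest`: a tibble with one
#'   row per group pair (`group1`, `group2`, `statistic`, `p_value`,
#'   `p_fw`, `session`, `B`), with the null matrix in attribute `"null"`.
#' @export
pc1_pairwise_test <- function(session_metrics, session, B = 10000,
                              vars = mwm_metric_vars, seed = NULL) {
  if (B < 1) stop("`B` must be at least 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- .perm_setup(session_metrics, vars)
  target <- match(session, st$sessions)
  if (is.na(target)) stop("Session not present in the data.", call. = FALSE)
  n_groups <- length(st$groups); n_sessions <- length(st$sessions)
  sizes <- tabulate(st$g_of_subject, n_groups)
  if (any(sizes < 2)) {
    stop("Every group needs at least 2 subjects for a t statistic.",
         call. = FALSE)
  }
  pairs <- utils::combn(n_groups, 2)
  pair_t <- function(stats) {
    vapply(seq_len(ncol(pairs)), function(j) {
      .welch_t(stats$pc1_by_group[[as.character(pairs[1, j])]],
               stats$pc1_by_group[[as.character(pairs[2, j])]])
    }, numeric(1))
  }
  flip_idx <- match("gallagher", vars)
  if (is.na(flip_idx)) flip_idx <- NULL
  obs <- pair_t(.assignment_stats(st$X, st$row_subject, st$row_session_idx,
                                  st$g_of_subject, n_groups, n_sessions,
                                  target_session = target,
                                  pc1_flip_idx = flip_idx))
  n_subj <- length(st$subjects)
  null <- matrix(0, B, ncol(pairs))
  for (b in seq_len(B)) {
    g_perm <- st$g_of_subject[sample.int(n_subj)]
    null[b, ] <- pair_t(.assignment_stats(st$X, st$row_subject,
                                          st$row_session_idx, g_perm,
                                          n_groups, n_sessions,
                                          target_session = target,
                                          pc1_flip_idx = flip_idx))
  }
  max_abs_null <- apply(abs(null), 1, max)
  out <- tibble::tibble(
    group1 = st$groups[pairs[1, ]],
    group2 = st$groups[pairs[2, ]],
    session = session,
    statistic = obs,
    p_value = vapply(seq_along(obs), function(j) {
      (1 + sum(abs(null[, j]) >= abs(obs[j]))) / (1 + B)
    }, numeric(1)),
    p_fw = vapply(seq_along(obs), function(j) {
      (1 + sum(max_abs_null >= abs(obs[j]))) / (1 + B)
    }, numeric(1)),
    B = B
  )
  attr(out, "null") <- null
  attr(out, "seed") <- seed
  class(out) <- c("mwm_pairwise_permtest", class(out))
  out
}

#' @export
print.mwm_permtest <- function(x, ...) {
  cat("<mwm_permtest> ", x$statistic_kind, "\n", sep = "")
  cat(sprintf("  observed = %.3f, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}

#' @describeIn separation_test Tidy the test into a one-row tibble.
#' @param x An `mwm_permtest` object.
#' @param ... Unused.
#' @export
tidy.mwm_permtest <- function(x, ...) {
  tibble::tibble(
    statistic_kind = x$statistic_kind,
    observed = x$observed,
    B = x$B,
    p_value = x$p_value
  )
}
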