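# Shared fixtures, all built in code.

tiny_geometry <- function(...) mwm_geometry(...)

# A design with k groups of n subjects each (subset of the default table).
small_design <- function(n_per_group = 4, k = 8, ...) {
  gr <- mwm_default_groups(n = rep(n_per_group, 8))[seq_len(k), ]
  mwm_design(groups = gr, ...)
}

# A trajectory tibble from bare coordinates, for metric unit tests.
make_track <- function(x, y, t = seq_along(x) / 10, subject = "s1",
                       group = "g1", phase = "acquisition", session = 1L,
                       trial = 1L, start_point = "N") {
  tibble::tibble(
    subject_id = subject, group = group, genotype = "WT", treatment = "NT",
    phase = phase, session = session, trial = trial,
    start_point = start_point, censored = NA, t = t, x = x, y = y
  )
}

# Session-metric rows from explicit values (defaults fill the other vars).
make_session_metrics <- function(df) {
  defaults <- list(latency = 30, gallagher = 40, whishaw = 50,
                   thigmotaxis = 40, quadrant_time = 30, distance = 600,
                   speed = 20, censored = FALSE, phase = "acquisition")
  for (v in names(defaults)) {
    if (!v %in% names(df)) df[[v]] <- defaults[[v]]
  }
  tibble::as_tibble(df)
}

# Simulated fixture for the censored random-intercept model.
make_censored_data <- function(n_subj = 50, n_sess = 5, beta0 = 3.2,
                               slope = -0.15, slope_b = -0.1, sigma_u = 0.5,
                               sigma_e = 0.45, threshold = Inf, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(n_subj)), each = n_sess),
    session = rep(seq_len(n_sess), n_subj),
    group = rep(rep(c("A", "B"), length.out = n_subj), each = n_sess)
  )
  u <- rep(stats::rnorm(n_subj, 0, sigma_u), each = n_sess)
  y <- beta0 + slope * df$session + slope_b * df$session * (df$group == "B") +
    u + stats::rnorm(nrow(df), 0, sigma_e)
  df$censored <- y >= threshold
  df$y <- pmin(y, threshold)
  df
}

# PCA-free variance decomposition oracle: everything straight from the
# Z-scored tables (population scaling), no eigendecomposition anywhere.
brute_force_decomposition <- function(median_table, individuals,
                                      vars = mwm_metric_vars) {
  M <- as.matrix(median_table[, vars])
  ctr <- colMeans(M)
  scl <- sqrt(colMeans(sweep(M, 2, ctr)^2))
  Z <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  nv <- length(vars)
  v_b <- sum(Z^2) / (nv * nrow(Z))
  sessions <- sort(unique(median_table$session))
  d2 <- vapply(sessions, function(s) {
    sum(colMeans(Z[median_table$session == s, , drop = FALSE])^2)
  }, numeric(1))
  v_bs <- sum(d2) / (nv * length(sessions))
  Zi <- sweep(sweep(as.matrix(individuals[, vars]), 2, ctr), 2, scl, "/")
  v_t <- sum(Zi^2) / (nv * nrow(Zi))
  list(v_total = v_t, v_between = v_b, v_between_session = v_bs,
       v_within_session = v_b - v_bs)
}
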