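test_that("group medians use the midpoint convention and full cell coverage", {
  sm <- make_session_metrics(tibble::tibble(
    subject_id = c("a", "b", "c"), group = "g1", session = 1L,
    latency = c(1, 2, 100)
  ))
  expect_equal(group_median_table(sm, vars = "latency")$latency, 2)
  sm2 <- make_session_metrics(tibble::tibble(
    subject_id = letters[1:4], group = "g1", session = 1L,
    latency = c(1, 2, 3, 4)
  ))
  expect_equal(group_median_table(sm2, vars = "latency")$latency, 2.5)
  # 8 groups x 5 sessions -> 40 rows
  d <- mwm_design(seed = 51)
  tbl <- simulate_metric_table(d)
  expect_equal(nrow(group_median_table(tbl)), 40)
  # empty cell errors name the cell
  sm3 <- dplyr::filter(tbl, !(group == "TS-NT" & session == 3))
  expect_error(group_median_table(sm3), "TS-NT, 3")
})

test_that("two-variable tables match closed-form correlation eigenvalues", {
  set.seed(52)
  n <- 40
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  md <- tibble::tibble(group = rep(letters[1:8], each = 5),
                       session = rep(1:5, 8), a = x1, b = x2)
  fit <- mwm_pca(md, vars = c("a", "b"))
  # population correlation of the realized sample
  zx <- (x1 - mean(x1)) / sqrt(mean((x1 - mean(x1))^2))
  zy <- (x2 - mean(x2)) / sqrt(mean((x2 - mean(x2))^2))
  r <- mean(zx * zy)
  expect_equal(fit$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-12)
  expect_equal(fit$pct_var[1], 100 * (1 + abs(r)) / 2, tolerance = 1e-12)
  # perfectly correlated pair: PC1 explains everything
  md2 <- dplyr::mutate(md, b = 2 * a + 3)
  fit2 <- mwm_pca(md2, vars = c("a", "b"))
  expect_equal(fit2$pct_var[1], 100, tolerance = 1e-9)
})

test_that("scores preserve distances and reconstruct the Z-scored table", {
  d <- mwm_design(seed = 53)
  md <- group_median_table(simulate_metric_table(d))
  fit <- mwm_pca(md)
  X <- as.matrix(md[, mwm_metric_vars])
  Z <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  S <- as.matrix(fit$scores[, paste0("PC", 1:7)])
  expect_equal(as.matrix(dist(S)), as.matrix(dist(Z)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(S %*% t(fit$loadings), Z, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(fit$eigenvalues), 7, tolerance = 1e-12)
  expect_equal(sum(fit$pct_var), 100, tolerance = 1e-12)
  expect_equal(colSums(fit$contributions), rep(100, 7), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(t(fit$loadings) %*% fit$loadings, diag(7), tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigenvalues sorted descending and non-negative
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= -1e-12))
})

test_that("eigenvalues agree with an independent eigendecomposition", {
  set.seed(54)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 7), 40, 7) %*% diag(runif(7, 0.5, 3))
    md <- dplyr::bind_cols(
      tibble::tibble(group = rep(letters[1:8], each = 5),
                     session = rep(1:5, 8)),
      tibble::as_tibble(stats::setNames(as.data.frame(X), mwm_metric_vars))
    )
    fit <- mwm_pca(md)
    Z <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
    ev <- eigen(crossprod(Z) / nrow(Z), symmetric = TRUE)
    expect_equal(fit$eigenvalues, ev$values, tolerance = 1e-10)
    # loadings match the eigenvectors up to sign
    agree <- abs(colSums(fit$loadings * ev$vectors))
    expect_equal(agree, rep(1, 7), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("component orientation is deterministic and learning-aligned", {
  d <- mwm_design(seed = 55)
  fit <- mwm_pca(group_median_table(simulate_metric_table(d)))
  expect_lte(fit$loadings["gallagher", "PC1"], 0)
  expect_gte(fit$loadings["speed", "PC2"], 0)
})

test_that("supplementary projection is exact, centered and affine", {
  d <- mwm_design(seed = 56)
  tbl <- simulate_metric_table(d)
  md <- group_median_table(tbl)
  fit <- mwm_pca(md)
  # a median row projects to its own score
  proj <- project_supplementary(md, fit)
  expect_equal(as.matrix(proj[, paste0("PC", 1:7)]),
               as.matrix(fit$scores[, paste0("PC", 1:7)]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the center maps to the origin
  ctr <- tibble::as_tibble(as.list(fit$center))
  p0 <- project_supplementary(ctr, fit)
  expect_equal(unlist(p0[, paste0("PC", 1:7)]), rep(0, 7),
               tolerance = 1e-12, ignore_attr = TRUE)
  # affine: project(a*x + (1-a)*y) = a proj(x) + (1-a) proj(y)
  a <- 0.3
  x1 <- md[3, mwm_metric_vars]; y1 <- md[17, mwm_metric_vars]
  mix <- a * x1 + (1 - a) * y1
  pm <- as.matrix(project_supplementary(mix, fit)[, paste0("PC", 1:7)])
  px <- as.matrix(project_supplementary(x1, fit)[, paste0("PC", 1:7)])
  py <- as.matrix(project_supplementary(y1, fit)[, paste0("PC", 1:7)])
  expect_equal(pm, a * px + (1 - a) * py, tolerance = 1e-9)
  # the full default cohort yields 86 x 5 = 430 supplementary points
  supp <- project_supplementary(tbl, fit)
  expect_equal(nrow(supp), 430)
  expect_error(project_supplementary(md[, -3], fit), "Missing variable")
})

test_that("group PC1 trajectories advance with learning", {
  d <- mwm_design(seed = 57)
  fit <- mwm_pca(group_median_table(simulate_metric_table(d)))
  tr <- pc_trajectories(fit)
  ok <- tr |>
    dplyr::group_by(group) |>
    dplyr::summarise(mono = all(diff(PC1) > -0.2), .groups = "drop")
  expect_true(all(ok$mono))
  # single-session table: trajectories of length 1
  d1 <- mwm_design(n_sessions = 1, seed = 57)
  fit1 <- mwm_pca(group_median_table(simulate_metric_table(d1)))
  expect_equal(nrow(pc_trajectories(fit1)), 8)
})

test_that("degenerate median tables are rejected", {
  md <- tibble::tibble(group = rep(c("a", "b"), each = 2), session = rep(1:2, 2),
                       u = c(1, 2, 3, 4), v = 5)
  expect_error(mwm_pca(md, vars = c("u", "v")), "Zero-variance")
  expect_error(mwm_pca(md[1, ], vars = c("u", "v")), "at least 2 rows")
})

test_that("tidiers and plots expose the fitted ordination", {
  d <- mwm_design(seed = 58)
  fit <- mwm_pca(group_median_table(simulate_metric_table(d)))
  td <- tidy(fit)
  expect_equal(nrow(td), 49)
  expect_true(all(c("variable", "component", "loading", "contribution")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 40)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_contributions(fit), "ggplot")
})
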