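test_that("without censoring or random effects the fit equals OLS", {
  df <- make_censored_data(n_subj = 20, sigma_u = 0, seed = 2)
  fit <- fit_censored_lmm(df, "y", random_intercept = FALSE)
  ols <- stats::lm(y ~ session * group, df)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma_e,
               sqrt(mean(residuals(ols)^2)), tolerance = 1e-4)
})

test_that("the censored fixed-effects path matches a Tobit oracle", {
  skip_if_not_installed("survival")
  df <- make_censored_data(n_subj = 30, sigma_u = 0, threshold = 2.6, seed = 3)
  expect_gt(mean(df$censored), 0.1)
  fit <- fit_censored_lmm(df, "y", threshold = 2.6, random_intercept = FALSE)
  sv <- survival::survreg(survival::Surv(y, !censored) ~ session * group,
                          data = df, dist = "gaussian")
  expect_equal(fit$coefficients$estimate, unname(coef(sv)), tolerance = 1e-4)
  expect_equal(fit$sigma_e, sv$scale, tolerance = 1e-4)
})

test_that("the uncensored random-intercept path matches lme4 ML", {
  skip_if_not_installed("lme4")
  df <- make_censored_data(n_subj = 30, sigma_u = 0.8, seed = 4)
  fit <- fit_censored_lmm(df, "y")
  lmm <- lme4::lmer(y ~ session * group + (1 | subject_id), df, REML = FALSE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(lmm)),
               tolerance = 1e-4)
  expect_equal(fit$sigma_u,
               unname(attr(lme4::VarCorr(lmm)$subject_id, "stddev")),
               tolerance = 1e-3)
  expect_equal(fit$sigma_e, stats::sigma(lmm), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lmm)), tolerance = 1e-5)
})

test_that("likelihood is additive over independent subjects", {
  df <- make_censored_data(n_subj = 16, threshold = 2.8, seed = 5)
  fit1 <- fit_censored_lmm(df, "y", threshold = 2.8)
  df2 <- rbind(df, transform(df, subject_id = paste0(subject_id, "_copy")))
  fit2 <- fit_censored_lmm(df2, "y", threshold = 2.8)
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-3)
  expect_equal(fit2$logLik, 2 * fit1$logLik, tolerance = 1e-3)
})

test_that("estimates are stable in the quadrature order", {
  df <- make_censored_data(n_subj = 40, threshold = 2.8, seed = 6)
  f16 <- fit_censored_lmm(df, "y", threshold = 2.8, quad_order = 16)
  f64 <- fit_censored_lmm(df, "y", threshold = 2.8, quad_order = 64)
  expect_lt(max(abs(f16$coefficients$estimate - f64$coefficients$estimate)),
            1e-4)
})

test_that("degenerate censored inputs raise errors", {
  df <- make_censored_data(n_subj = 10, threshold = 2.8, seed = 7)
  df_all <- transform(df, censored = TRUE, y = 2.8)
  expect_error(fit_censored_lmm(df_all, "y", threshold = 2.8),
               "not identifiable")
  expect_error(
    fit_censored_lmm(df[, setdiff(names(df), "censored")], "y",
                     threshold = 2.8),
    "censored")
  expect_error(fit_censored_lmm(df, "y", threshold = 2.8, reference = "zz"),
               "not a group label")
})

test_that("Wald p-values are approximately uniform under the null", {
  # no-random-effect fits are fast enough for a replicate sweep
  set.seed(8)
  pv <- replicate(300, {
    df <- make_censored_data(n_subj = 16, n_sess = 3, slope_b = 0,
                             sigma_u = 0, threshold = 3.1,
                             seed = sample.int(1e6, 1))
    fit <- fit_censored_lmm(df, "y", threshold = 3.1,
                            random_intercept = FALSE, n_starts = 1)
    fit$coefficients$p_value[fit$coefficients$term == "session:groupB"]
  })
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pv < 0.05), 0.01)
  expect_lt(mean(pv < 0.05), 0.12)
})

test_that("the latency wrapper censors on the log scale", {
  d <- small_design(n_per_group = 4, k = 4, seed = 9)
  tbl <- simulate_metric_table(d)
  fit <- fit_latency_model(tbl, cutoff = 60, reference = d$groups$group[1])
  expect_equal(fit$threshold, log(60))
  expect_identical(fit$reference, d$groups$group[1])
  expect_true(all(grepl("^session:", fit$coefficients$term[
    !is.na(fit$coefficients$p_bh)])))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 16)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("ANOVA group effects match a hand-worked oracle", {
  # 3 groups x 2 subjects x 2 sessions, analyzable by explicit sums of squares
  df <- make_session_metrics(tibble::tibble(
    subject_id = rep(c("a1", "a2", "b1", "b2", "c1", "c2"), each = 2),
    group = rep(c("A", "B", "C"), each = 4),
    session = rep(1:2, 6),
    latency = c(10, 12, 14, 16, 20, 22, 26, 28, 30, 34, 38, 42)
  ))
  res <- rm_anova_posthoc(df, "latency")
  # oracle: between-subject stratum sums of squares from subject totals
  subj_mean <- tapply(df$latency, df$subject_id, mean)
  grp_of <- rep(c("A", "B", "C"), each = 2)
  grand <- mean(df$latency)
  ss_group <- 4 * sum((tapply(df$latency, df$group, mean) - grand)^2)
  ss_subj_within <- 2 * sum((subj_mean - tapply(df$latency, df$group,
                                                mean)[grp_of])^2)
  f_oracle <- (ss_group / 2) / (ss_subj_within / 3)
  expect_equal(res$overall$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(res$overall$df1, 2)
  expect_equal(res$overall$df2, 3)
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$p_bh >= res$posthoc$p_tukey - 1e-12))
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("identical groups yield a null ANOVA result", {
  set.seed(10)
  df <- make_session_metrics(tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:12), each = 3),
    group = rep(c("A", "B", "C"), each = 12),
    session = rep(1:3, 12),
    latency = rnorm(36, 30, 5)
  ))
  res <- rm_anova_posthoc(df, "latency")
  expect_gt(res$overall$p_value, 0.05)
})

test_that("BH adjustment reproduces the hand-worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone: raising a raw p never lowers any adjusted p
  set.seed(11)
  p <- runif(10)
  adj <- bh_adjust(p)
  p2 <- p; p2[4] <- min(1, p2[4] + 0.2)
  expect_true(all(bh_adjust(p2) >= adj - 1e-12))
})
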