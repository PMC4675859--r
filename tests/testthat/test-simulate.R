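test_that("fully goal-directed noise-free trials swim straight to the platform", {
  g <- mwm_geometry()
  set.seed(1)
  tr <- simulate_trial(g, goal_bias = 1, thigmotaxis_weight = 0, speed = 25,
                       heading_sd = 0)
  expect_false(attr(tr, "censored"))
  # straight path: travelled distance matches the start-to-contact chord
  start <- attr(tr, "start_xy")
  chord <- sqrt(sum((c(tr$x[nrow(tr)], tr$y[nrow(tr)]) - start)^2))
  expect_equal(path_length(c(start[1], tr$x), c(start[2], tr$y)), chord,
               tolerance = 1e-6)
  w <- whishaw_index(c(start[1], tr$x), c(start[2], tr$y), start,
                     g$platform_center, g$corridor_half_width)
  expect_gte(w, 95)
  # released at the wall, so the straight approach necessarily crosses the
  # peripheral band once; after leaving it the swim never re-enters
  r <- sqrt(tr$x^2 + tr$y^2)
  out_band <- which(r < g$pool_radius - g$periphery_band_width)
  expect_gt(length(out_band), 0)
  expect_equal(thigmotaxis_index(tr$x[out_band[1]:nrow(tr)],
                                 tr$y[out_band[1]:nrow(tr)],
                                 g$pool_radius, g$periphery_band_width), 0)
})

test_that("pure wall-followers stay in the periphery and never escape", {
  g <- mwm_geometry()
  set.seed(2)
  tr <- simulate_trial(g, goal_bias = 0, thigmotaxis_weight = 1, speed = 20)
  expect_true(attr(tr, "censored"))
  expect_equal(nrow(tr), 600)
  r <- sqrt(tr$x^2 + tr$y^2)
  expect_true(all(r >= g$pool_radius - g$periphery_band_width))
})

test_that("trials are deterministic under a fixed seed", {
  g <- mwm_geometry()
  set.seed(7)
  a <- simulate_trial(g, goal_bias = 0.4, thigmotaxis_weight = 0.3, speed = 20)
  set.seed(7)
  b <- simulate_trial(g, goal_bias = 0.4, thigmotaxis_weight = 0.3, speed = 20)
  expect_identical(a, b)
})

test_that("invalid trial parameters are rejected", {
  g <- mwm_geometry()
  expect_error(simulate_trial(g, 0.5, 0.1, speed = -2), "speed")
  expect_error(simulate_trial(g, 0.8, 0.5, speed = 10), "sum to at most 1")
  expect_error(simulate_trial(g, 0.5, 0.1, speed = 10, start = "Q"))
})

test_that("cohort schedule matches the protocol exactly", {
  d <- small_design(n_per_group = 2, k = 1, seed = 5)
  g <- mwm_geometry()
  trk <- simulate_cohort(d, g)
  trials <- dplyr::distinct(trk, subject_id, phase, session, trial)
  # 1 pretraining + 5x4 acquisition + 1 probe + 1 cued + 3x4 reversal = 35
  expect_equal(nrow(trials), 2 * 35)
  acq <- dplyr::filter(trials, phase == "acquisition")
  expect_equal(nrow(acq), 2 * 20)
  # starts within a session are a permutation of the four release points
  starts <- trk |>
    dplyr::filter(phase == "acquisition") |>
    dplyr::distinct(subject_id, session, trial, start_point) |>
    dplyr::group_by(subject_id, session) |>
    dplyr::summarise(ok = setequal(start_point, c("N", "S", "E", "W")),
                     .groups = "drop")
  expect_true(all(starts$ok))
  # probe trials last exactly the full cutoff
  probe <- dplyr::filter(trk, phase == "probe")
  expect_equal(unique(table(probe$subject_id)), 600L)
  expect_true(all(probe$censored))
})

test_that("the default cohort covers the published group sizes", {
  d <- mwm_design()
  expect_equal(d$groups$n, c(10L, 11L, 14L, 11L, 11L, 9L, 12L, 8L))
  expect_equal(sum(d$groups$n), 86L)
  # 86 subjects x 5 sessions x 4 trials = 1720 acquisition trials by schedule
  expect_equal(sum(d$groups$n) * d$n_sessions * d$trials_per_session, 1720L)
})

test_that("every sample lies inside the pool", {
  d <- small_design(n_per_group = 2, k = 4, seed = 9)
  g <- mwm_geometry()
  trk <- simulate_cohort(d, g, phases = c("acquisition", "probe"))
  expect_true(all(trk$x^2 + trk$y^2 <= g$pool_radius^2 * (1 + 1e-12)))
})

test_that("cohorts are reproducible and subject streams are isolated", {
  g <- mwm_geometry()
  d1 <- small_design(n_per_group = 2, k = 2, seed = 11)
  a <- simulate_cohort(d1, g, phases = "acquisition")
  b <- simulate_cohort(d1, g, phases = "acquisition")
  expect_identical(a, b)
  # different seed: same schedule, different trajectories
  d2 <- small_design(n_per_group = 2, k = 2, seed = 12)
  c2 <- simulate_cohort(d2, g, phases = "acquisition")
  expect_identical(dplyr::distinct(a, subject_id, session, trial),
                   dplyr::distinct(c2, subject_id, session, trial))
  expect_false(identical(a$x, c2$x))
  # growing group 1 leaves group 2's subjects untouched
  gr <- mwm_default_groups(n = rep(2, 8))[1:2, ]
  gr_big <- gr; gr_big$n[1] <- 4L
  small <- simulate_cohort(mwm_design(groups = gr, seed = 11), g,
                           phases = "acquisition")
  big <- simulate_cohort(mwm_design(groups = gr_big, seed = 11), g,
                         phases = "acquisition")
  sid <- gr$group[2]
  s_small <- dplyr::filter(small, group == sid)
  s_big <- dplyr::filter(big, group == sid)
  expect_identical(s_small$x, s_big$x)
})

test_that("group-mean latency does not increase across sessions in expectation", {
  # one strongly learning group, many subjects; sampling error bound 2 SE
  gr <- mwm_default_groups(n = c(200, rep(2, 7)))[1, ]
  d <- mwm_design(groups = gr, seed = 21)
  g <- mwm_geometry()
  trk <- simulate_cohort(d, g, phases = "acquisition")
  m <- trial_metrics(trk, g)
  bysess <- m |>
    dplyr::group_by(session) |>
    dplyr::summarise(mean_lat = mean(latency),
                     se = stats::sd(latency) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::arrange(session)
  for (s in seq_len(nrow(bysess) - 1)) {
    expect_lte(bysess$mean_lat[s + 1],
               bysess$mean_lat[s] + 2 * (bysess$se[s] + bysess$se[s + 1]))
  }
})
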