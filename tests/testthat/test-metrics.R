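test_that("latency is the time of first platform contact", {
  g <- mwm_geometry()
  p <- g$platform_center
  # approach that enters the platform exactly at sample 123
  n <- 200
  x <- rep(p[1] + 50, n); y <- rep(p[2], n)
  x[123:n] <- p[1]
  lat <- trial_latency(seq_len(n) / 10, x, y, p, g$platform_radius)
  expect_equal(lat$latency, 12.3)
  expect_false(lat$censored)
  # never reaching: censored at the cutoff
  lat2 <- trial_latency(seq_len(600) / 10, rep(p[1] + 50, 600),
                        rep(p[2], 600), p, g$platform_radius)
  expect_equal(lat2$latency, 60)
  expect_true(lat2$censored)
  # immediate contact at the first sample
  lat3 <- trial_latency(0.1, p[1], p[2], p, g$platform_radius)
  expect_equal(lat3$latency, 0.1)
})

test_that("path length and speed follow uniform motion and closed forms", {
  # straight 100 cm in 10 s
  x <- seq(0, 100, length.out = 101)
  expect_equal(path_length(x, rep(0, 101)), 100)
  # stationary animal
  expect_equal(path_length(rep(3, 50), rep(4, 50)), 0)
  # circle of radius 50 at 360 points: inscribed-polygon perimeter oracle
  th <- seq(0, 2 * pi, length.out = 361)
  d <- path_length(50 * cos(th), 50 * sin(th))
  oracle <- 2 * 360 * 50 * sin(pi / 360)
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_equal(d, 2 * pi * 50, tolerance = 1e-4)
})

test_that("Gallagher index averages distances in 1-second blocks", {
  goal <- c(10, -20)
  # constant distance 30 cm
  th <- seq(0, 4 * pi, length.out = 120)
  expect_equal(gallagher_index(goal[1] + 30 * cos(th), goal[2] + 30 * sin(th),
                               goal), 30, tolerance = 1e-9)
  # linear approach 50 -> 0 cm over 5 s: brute-force block oracle
  k <- 1:50
  d_k <- 50 - k                      # distance at sample k
  x <- goal[1] + d_k; y <- rep(goal[2], 50)
  oracle <- mean(vapply(split(d_k, (k - 1) %/% 10), mean, numeric(1)))
  expect_equal(oracle, 24.5)
  expect_equal(gallagher_index(x, y, goal), oracle, tolerance = 1e-12)
  # trailing partial block averaged over its own length
  k2 <- 1:25
  d2 <- 25 - k2
  oracle2 <- mean(vapply(split(d2, (k2 - 1) %/% 10), mean, numeric(1)))
  expect_equal(gallagher_index(goal[1] + d2, rep(goal[2], 25), goal), oracle2,
               tolerance = 1e-12)
})

test_that("Gallagher index is rotation invariant", {
  set.seed(4)
  x <- runif(100, -60, 60); y <- runif(100, -60, 60)
  goal <- c(30, 25)
  base <- gallagher_index(x, y, goal)
  for (ang in c(0.3, 1.2, 2.9)) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    xy <- cbind(x, y) %*% t(Rm)
    goal_r <- as.vector(Rm %*% goal)
    expect_equal(gallagher_index(xy[, 1], xy[, 2], goal_r), base,
                 tolerance = 1e-9)
  }
})

test_that("Whishaw index measures the in-corridor share of the path", {
  start <- c(0, 0); goal <- c(100, 0); w <- 10
  # straight start->goal path
  x <- seq(0, 100, length.out = 51)
  expect_equal(whishaw_index(x, rep(0, 51), start, goal, w), 100)
  # path entirely outside the corridor
  expect_equal(whishaw_index(x, rep(30, 51), start, goal, w), 0)
  # 40 cm inside then 60 cm leaving the corridor: 40%
  expect_equal(whishaw_index(c(0, 40, 40), c(0, 0, 60), start, goal, w), 40)
  expect_error(whishaw_index(x, rep(0, 51), c(1, 1), c(1, 1), w), "differ")
})

test_that("Whishaw corridor membership agrees with a brute-force capsule test", {
  set.seed(5)
  start <- c(-40, 10); goal <- c(55, -30); w <- 14
  x <- runif(200, -80, 80); y <- runif(200, -80, 80)
  # naive point-in-capsule: dense sampling of the segment
  tt <- seq(0, 1, length.out = 20001)
  segx <- start[1] + tt * (goal[1] - start[1])
  segy <- start[2] + tt * (goal[2] - start[2])
  naive_in <- vapply(seq_along(x), function(i) {
    min(sqrt((segx - x[i])^2 + (segy - y[i])^2)) <= w + 1e-6
  }, logical(1))
  fast_in <- mwmpca:::dist_to_segment(x, y, start, goal) <= w
  expect_equal(fast_in, naive_in)
  # index computed from the oracle membership matches the function
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  both <- naive_in[-length(naive_in)] & naive_in[-1]
  expect_equal(whishaw_index(x, y, start, goal, w),
               100 * sum(steps[both]) / sum(steps), tolerance = 1e-9)
})

test_that("Whishaw index is invariant under rigid motions", {
  set.seed(6)
  x <- runif(80, -50, 50); y <- runif(80, -50, 50)
  start <- c(-30, 0); goal <- c(40, 20); w <- 12
  base <- whishaw_index(x, y, start, goal, w)
  ang <- 1.1; shift <- c(12, -7)
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  xy <- sweep(cbind(x, y) %*% t(Rm), 2, -shift)
  expect_equal(
    whishaw_index(xy[, 1], xy[, 2],
                  as.vector(Rm %*% start) + shift,
                  as.vector(Rm %*% goal) + shift, w),
    base, tolerance = 1e-9
  )
})

test_that("thigmotaxis counts samples in the peripheral band", {
  R <- 85; bw <- 17
  expect_equal(thigmotaxis_index(rep(84, 10), rep(0, 10), R, bw), 100)
  expect_equal(thigmotaxis_index(rep(0, 10), rep(0, 10), R, bw), 0)
  # alternating inside/outside: exactly half
  r <- rep(c(80, 10), 25)
  expect_equal(thigmotaxis_index(r, rep(0, 50), R, bw), 50)
})

test_that("quadrant occupancy shares always sum to 100", {
  q <- quadrant_occupancy(rep(10, 5), rep(20, 5))
  expect_equal(unname(q), c(100, 0, 0, 0))
  # uniform circle crossing all quadrants symmetrically
  th <- (0:359) * pi / 180
  q2 <- quadrant_occupancy(cos(th), sin(th))
  expect_equal(unname(q2), rep(25, 4))
  set.seed(8)
  q3 <- quadrant_occupancy(rnorm(101), rnorm(101))
  expect_equal(sum(q3), 100, tolerance = 1e-9)
})

test_that("session means average trials and AND the censored flags", {
  m <- tibble::tibble(
    subject_id = "s1", group = "g", phase = "acquisition", session = 1L,
    trial = 1:4,
    latency = c(10, 20, 30, 60), gallagher = c(10, 20, 30, 40),
    whishaw = 50, thigmotaxis = 20, quadrant_time = 25,
    distance = c(100, 200, 300, 600), speed = 10,
    censored = c(FALSE, FALSE, FALSE, TRUE)
  )
  sm <- session_metrics(m)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$latency, 30)
  expect_equal(sm$gallagher, 25)
  expect_false(sm$censored)
  # all trials censored -> censored session
  m2 <- dplyr::mutate(m, censored = TRUE)
  expect_true(session_metrics(m2)$censored)
  # invariant to trial relabeling
  m3 <- dplyr::mutate(m[c(3, 1, 4, 2), ], trial = 1:4)
  expect_equal(session_metrics(m3)$latency, sm$latency)
  # idempotent on identical trials
  m4 <- dplyr::mutate(m, latency = 12, censored = FALSE)
  expect_equal(session_metrics(m4)$latency, 12)
})

test_that("cued exclusion applies the 30 s rule inclusively", {
  m <- make_session_metrics(tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    group = "g", session = 1L,
    phase = "cued",
    latency = c(29.9, 30.0, 60, 5),
    censored = c(FALSE, FALSE, TRUE, FALSE)
  ))
  expect_setequal(cued_exclusions(m), c("b", "c"))
})

test_that("trial metrics integrate the per-trial computations", {
  d <- small_design(n_per_group = 2, k = 2, seed = 31)
  g <- mwm_geometry()
  trk <- simulate_cohort(d, g, phases = c("acquisition", "probe"))
  m <- trial_metrics(trk, g)
  expect_equal(nrow(m), 2 * 2 * (20 + 1))
  expect_true(all(m$latency > 0 & m$latency <= 60))
  expect_true(all(m$whishaw >= 0 & m$whishaw <= 100))
  expect_true(all(m$thigmotaxis >= 0 & m$thigmotaxis <= 100))
  expect_true(all(m$quadrant_time >= 0 & m$quadrant_time <= 100))
  # censored iff latency at the cutoff
  expect_equal(m$censored, m$latency == 60)
  # speed x latency recovers distance
  expect_equal(m$speed * m$latency, m$distance, tolerance = 1e-9)
})
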