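# independent brute-force oracles ------------------------------------------

oracle_delta_social <- function(counts, current) {
  best_alt <- -Inf
  for (s in c("A", "B", "C", "D")) {
    if (s != current && counts[[s]] > best_alt) best_alt <- counts[[s]]
  }
  best_alt - counts[[current]]
}

oracle_mean_pairwise <- function(x, y) {
  n <- length(x)
  acc <- 0; m <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      acc <- acc + sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      m <- m + 1
    }
  }
  acc / m
}

test_that("DeltaSocial matches its definition and the brute-force oracle", {
  expect_equal(delta_social(c(A = 9, B = 0, C = 0, D = 0), "A"), -9)
  expect_equal(delta_social(c(A = 2, B = 4, C = 1, D = 0), "A"), 2)
  expect_error(delta_social(c(A = 1, B = 1, C = 1, D = 1), NA), "no current")
  # exhaustive: every assignment of up to 4 others to sites, every focal
  grid <- expand.grid(A = 0:4, B = 0:4, C = 0:4, D = 0:4)
  grid <- grid[rowSums(grid) <= 4, ]
  for (i in seq_len(nrow(grid))) {
    counts <- unlist(grid[i, ])
    for (cur in c("A", "B", "C", "D")) {
      expect_equal(delta_social(counts, cur), oracle_delta_social(counts, cur))
    }
  }
})

test_that("DeltaSocial stays within [-(N-1), N-1] on simulated opinions", {
  cfg <- quick_config("global", "medium", n = 8)
  tr <- simulate_trial(cfg, agent_params(), seed = 31)$trajectories
  ops <- opinion_series(tr, cfg)
  ds <- add_delta_social(ops)
  vals <- ds$delta_social[!is.na(ds$delta_social)]
  expect_gt(length(vals), 0)
  expect_true(all(vals >= -(8 - 1) & vals <= 8 - 1))
})

test_that("inter-player distance equals the mean over all pairs", {
  expect_equal(interplayer_distance(c(0, 10), c(0, 0)), 10)
  side <- 5
  tri_x <- c(0, side, side / 2)
  tri_y <- c(0, 0, side * sqrt(3) / 2)
  expect_equal(interplayer_distance(tri_x, tri_y), side)
  expect_error(interplayer_distance(1, 1), "at least 2")
  withr::with_seed(5, {
    for (i in 1:25) {
      x <- stats::runif(6, -70, 70); y <- stats::runif(6, -70, 70)
      expect_equal(interplayer_distance(x, y), oracle_mean_pairwise(x, y))
    }
  })
})

test_that("distance to a site averages plain Euclidean distances", {
  site <- list(x = 40, y = 40)
  expect_equal(mean_distance_to_site(rep(40, 5), rep(40, 5), site), 0)
  expect_equal(mean_distance_to_site(0, 0, site), 40 * sqrt(2))
  withr::with_seed(8, {
    for (i in 1:25) {
      x <- stats::runif(7, -70, 70); y <- stats::runif(7, -70, 70)
      expect_equal(mean_distance_to_site(x, y, site),
                   mean(sqrt((x - 40)^2 + (y - 40)^2)))
    }
  })
})

test_that("COM distance matches hand values and a brute-force loop", {
  two <- synth_traj(list(stationary_fn(0, 0), stationary_fn(10, 0)), t = 0:2)
  expect_equal(com_distance(two, "P01", 1), 5)
  expect_equal(com_distance(two, "P02", 1), 5)
  withr::with_seed(12, {
    pos <- matrix(stats::runif(8 * 2, -70, 70), ncol = 2)
    fns <- purrr::map(seq_len(8), function(i) stationary_fn(pos[i, 1], pos[i, 2]))
    tr <- synth_traj(fns, t = 0:1)
    for (i in 1:8) {
      expect_equal(com_distance(tr, sprintf("P%02d", i), 0),
                   sqrt(sum((pos[i, ] - colMeans(pos))^2)))
    }
  })
  expect_error(com_distance(two, "P01", 99), "not in the table")
})

test_that("approach speed isolates the focal's own radial motion", {
  # stationary focal: zero
  fns <- c(list(stationary_fn(50, 0)),
           purrr::map(1:7, function(i) stationary_fn(0, 0)))
  tr0 <- synth_traj(fns, t = 0:4)
  expect_equal(approach_speed(tr0, "P01", 2), 0)
  # focal closing on 7 co-located others at 8 m/s: COM co-moves at v/8,
  # closing speed 8 * 7/8, times speed 8 -> 56
  fns <- c(list(function(t) c(100 - 8 * t, 0)),
           purrr::map(1:7, function(i) stationary_fn(0, 0)))
  tr <- synth_traj(fns, t = 0:4)
  expect_equal(approach_speed(tr, "P01", 2), 56)
  # circular motion about the others' centroid keeps |p - COM| constant
  fns <- c(list(function(t) c(30 * cos(0.2 * t), 30 * sin(0.2 * t))),
           purrr::map(1:7, function(i) stationary_fn(0, 0)))
  trc <- synth_traj(fns, t = 0:4)
  expect_equal(approach_speed(trc, "P01", 2), 0, tolerance = 1e-9)
  expect_error(approach_speed(tr, "P01", 0), "not inside")
})

test_that("negating the focal's motion flips the approach-speed sign", {
  others <- purrr::map(1:6, function(i) {
    stationary_fn(10 * cos(i), 10 * sin(i))
  })
  # same position at t = 2, exactly negated velocity
  fwd <- synth_traj(c(list(function(t) c(60 - 8 * t, 5)), others), t = 0:4)
  bwd <- synth_traj(c(list(function(t) c(28 + 8 * t, 5)), others), t = 0:4)
  a_fwd <- approach_speed(fwd, "P01", 2)
  a_bwd <- approach_speed(bwd, "P01", 2)
  expect_gt(a_fwd, 0)
  expect_equal(a_bwd, -a_fwd, tolerance = 1e-6)
})

test_that("the per-second metrics table carries consistent columns", {
  cfg <- quick_config("global", "easy", n = 7)
  tr <- simulate_trial(cfg, agent_params(), seed = 6)$trajectories
  t1 <- resample_1hz(tr)
  ops <- opinion_series(tr, cfg)
  met <- trial_metrics(t1, ops, cfg)
  expect_equal(nrow(met), nrow(t1))
  expect_true(all(c("delta_social", "com_dist", "approach_speed",
                    "interplayer_dist") %in% names(met)))
  expect_true(all(met$com_dist >= 0))
  expect_true(all(met$interplayer_dist > 0))
  # interior approach-speed values defined, ends NA
  one <- met[met$participant_id == "P01", ]
  expect_true(is.na(one$approach_speed[1]))
  expect_true(is.na(one$approach_speed[nrow(one)]))
  expect_false(anyNA(one$approach_speed[2:(nrow(one) - 1)]))
})
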