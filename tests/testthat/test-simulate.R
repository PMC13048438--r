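test_that("perception models the visibility conditions", {
  cfg <- quick_config("global", "easy")
  st <- agent_state(x = 0, y = 0)
  out <- perceive_sites(st, cfg)
  expect_equal(unname(out$perceived), cfg$sites$radius)  # zero noise

  lcfg <- quick_config("local", "easy")
  far <- perceive_sites(agent_state(x = 0, y = 0), lcfg)
  expect_true(all(is.na(far$perceived)))                 # all > 25 m away
  near <- perceive_sites(agent_state(x = 30, y = 30, noise = rep(0.5, 4)), lcfg)
  expect_equal(unname(near$perceived[c("A", "B", "C")]), rep(NA_real_, 3))
  expect_equal(unname(near$perceived[["D"]]), 15.5)      # revealed with noise
})

test_that("a degenerate hazard never switches and kinematics integrate exactly", {
  cfg <- quick_config("global", "easy", correct_site = "D")
  p <- agent_params(sigma_percept = 0, w_social = 0, beta_ds = 0,
                    beta_dist = 0, beta_time = 0, alpha = -1e9)
  st <- agent_state(x = 0, y = 0, heading = atan2(1, 1))
  st <- perceive_sites(st, cfg)
  st$target <- "D"
  st$goal_x <- 40; st$goal_y <- 40
  counts <- c(A = 0, B = 0, C = 0, D = 0)
  out <- withr::with_seed(1, agent_step(st, counts, p, cfg))
  expect_identical(out$target, "D")
  # already aligned with the goal: one tick covers exactly 8 m of diagonal
  expect_equal(sqrt(out$x^2 + out$y^2), 8, tolerance = 1e-9)
  expect_equal(out$y / out$x, 1, tolerance = 1e-9)
})

test_that("the switch hazard is a logistic in its covariates", {
  cfg <- quick_config("global", "easy", correct_site = "D")
  # alpha = 0, agent sitting on its target, no disagreement: p = 0.5
  p <- agent_params(sigma_percept = 0, w_social = 0, beta_ds = 0,
                    beta_dist = 0, beta_time = 0, alpha = 0)
  flips <- withr::with_seed(7, vapply(1:400, function(i) {
    st <- agent_state(x = 40, y = 40, target = "D", goal_x = 40, goal_y = 40)
    st <- perceive_sites(st, cfg)
    out <- agent_step(st, c(A = 0, B = 0, C = 0, D = 0), p, cfg)
    out$target != "D"
  }, logical(1)))
  expect_gt(mean(flips), 0.4)
  expect_lt(mean(flips), 0.6)
})

test_that("trials are deterministic given their seed", {
  cfg <- quick_config("informed_minority", "medium", n = 8)
  a <- simulate_trial(cfg, agent_params(), seed = 99)
  b <- simulate_trial(cfg, agent_params(), seed = 99)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$outcome, b$outcome)
})

test_that("noise-free asocial groups always find the largest site", {
  cfg <- quick_config("global", "hard", n = 7, correct_site = "B")
  p <- agent_params(sigma_percept = 0, w_social = 0)
  for (seed in 1:5) {
    out <- simulate_trial(cfg, p, seed = seed, return_trajectories = FALSE)$outcome
    expect_identical(out$consensus_site, "B")
    expect_identical(out$success, 1L)
    # straight-line travel from anywhere in the start disc takes under 15 s
    expect_lte(out$consensus_time, 15)
  }
})

test_that("simulated motion respects speed, turn and arena bounds", {
  cfg <- quick_config("local", "medium", n = 7)
  tr <- simulate_trial(cfg, agent_params(), seed = 13)$trajectories
  dt <- 1 / cfg$sample_rate
  by_pt <- split(tr, tr$participant_id)
  for (df in by_pt) {
    step <- sqrt(diff(df$x)^2 + diff(df$y)^2)
    expect_lte(max(step), cfg$speed * dt + 1e-6)
    turn <- abs(atan2(sin(diff(df$heading)), cos(diff(df$heading))))
    expect_lte(max(turn), cfg$rot_rate * dt + 1e-6)
  }
  expect_lte(max(abs(c(tr$x, tr$y))), cfg$arena_half_extent)
})

test_that("batches cross the design grid with reproducible manifests", {
  b1 <- simulate_batch(n_per_cell = 2, params = agent_params(),
                       master_seed = 17, keep_trajectories = FALSE,
                       n_participants = 7, sample_rate = 5)
  expect_equal(nrow(b1$outcomes), 18)   # 3 conditions x 3 difficulties x 2
  b2 <- simulate_batch(n_per_cell = 2, params = agent_params(),
                       master_seed = 17, keep_trajectories = FALSE,
                       n_participants = 7, sample_rate = 5)
  expect_identical(b1$outcomes, b2$outcomes)
  expect_equal(sort(unique(b1$outcomes$condition)),
               c("global", "informed_minority", "local"))
})
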