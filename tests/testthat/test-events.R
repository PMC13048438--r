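cfg_ev <- trial_config("global", "easy", n_participants = 7,
                       correct_site = "D")

moving_ops <- function(sites) {
  synth_opinions(sites, ifelse(is.na(sites), "none", "moving_toward"))
}

test_that("moving runs emit one non-terminal sample per second", {
  ops <- moving_ops(c("A", "A", "A"))
  ev <- build_moving_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t, c(0, 1))
  expect_equal(ev$switch, c(0L, 0L))
  expect_equal(ev$on_correct, c(0L, 0L))
})

test_that("a sustained change of supported site is a switch", {
  ops <- moving_ops(c("A", "A", "B", "B"))
  ev <- build_moving_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(ev$t, c(0, 1, 2))
  expect_equal(ev$switch, c(0L, 1L, 0L))
})

test_that("a one-second excursion is not a switch", {
  ops <- moving_ops(c("A", "B", "A"))
  ev <- build_moving_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(sum(ev$switch), 0L)
})

test_that("occupation seconds emit samples with a running clock", {
  # occupying frames t = 0..5 (the clock reaches 5 s); the first frame
  # initializes the clock, the terminal frame has no successor
  ops <- synth_opinions(rep("A", 6), rep("occupying", 6))
  ev <- build_still_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$time_passed, 1:4)
  expect_equal(ev$switch, rep(0L, 4))
})

test_that("a sustained departure marks the last occupying second", {
  ops <- synth_opinions(c("A", "A", "A", "B", "B", "B"),
                        c(rep("occupying", 3), rep("moving_toward", 3)))
  ev <- build_still_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(ev$t, c(1, 2))
  expect_equal(ev$switch, c(0L, 1L))
})

test_that("drifting off and re-occupying the same site is no switch", {
  ops <- synth_opinions(c("A", "A", "A", NA, "A", "A", "A"),
                        c(rep("occupying", 3), "none", rep("occupying", 3)))
  ev <- build_still_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(sum(ev$switch), 0L)
  # the clock restarts after the interruption
  expect_equal(ev$time_passed[ev$t == 5], 1)
})

test_that("merging concatenates disjoint tables and rejects duplicates", {
  m <- moving_ops(c("A", "A", "A"))
  s <- synth_opinions(rep("A", 6), rep("occupying", 6), participant = "P02")
  ev_m <- build_moving_events(m, synth_metrics(m), cfg_ev)
  ev_s <- build_still_events(s, synth_metrics(s), cfg_ev)
  both <- merge_events(ev_m, ev_s)
  expect_equal(nrow(both), nrow(ev_m) + nrow(ev_s))
  empty <- ev_s[0, ]
  expect_identical(merge_events(ev_m, empty), ev_m)
  expect_error(merge_events(ev_m, ev_m), "duplicate event keys")
})

test_that("every recorded switch is confirmed by the opinion series", {
  cfg <- quick_config("global", "medium", n = 8)
  tr <- simulate_trial(cfg, agent_params(), seed = 77)$trajectories
  ops <- opinion_series(tr, cfg)
  ev <- build_events(tr, cfg)
  sw <- ev[ev$switch == 1, ]
  for (i in seq_len(nrow(sw))) {
    mine <- ops[ops$participant_id == sw$participant_id[i], ]
    old_site <- mine$site[mine$t == sw$t[i]]
    nxt <- mine$site[mine$t %in% (sw$t[i] + 1:2)]
    expect_length(nxt, 2)
    expect_false(anyNA(nxt))
    expect_true(all(nxt == nxt[1]))       # sustained
    expect_false(nxt[1] == old_site)      # a genuine alternative
  }
})

test_that("noise-free asocial trials contain no switches at all", {
  cfg <- quick_config("global", "easy", n = 7)
  p <- agent_params(sigma_percept = 0, w_social = 0, beta_ds = 0,
                    beta_dist = 0, beta_time = 0, alpha = -1e9)
  for (seed in c(4, 5)) {
    tr <- simulate_trial(cfg, p, seed = seed)$trajectories
    ev <- build_events(tr, cfg)
    expect_gt(nrow(ev), 0)
    expect_equal(sum(ev$switch), 0L)
  }
})

test_that("event counts follow the run structure of the series", {
  # m whole seconds of moving support with k sustained switches:
  # every non-terminal supported second emits a sample, sum(switch) = k
  ops <- moving_ops(c("A", "A", "B", "B", "C", "C", "C"))
  ev <- build_moving_events(ops, synth_metrics(ops), cfg_ev)
  expect_equal(nrow(ev), 6)
  expect_equal(sum(ev$switch), 2L)
})
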