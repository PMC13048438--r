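# shared fixtures, all generated in code

quick_config <- function(condition = "global", difficulty = "easy", n = 7, ...) {
  trial_config(condition = condition, difficulty = difficulty,
               n_participants = n, ...)
}

# synthetic trajectory table: one row per participant per timestep, built
# from per-participant position functions of t
synth_traj <- function(pos_fns, t, trial_id = "T1", informed = NULL) {
  n <- length(pos_fns)
  ids <- sprintf("P%02d", seq_len(n))
  if (is.null(informed)) informed <- rep(FALSE, n)
  purrr::map2(pos_fns, seq_len(n), function(f, i) {
    xy <- t(vapply(t, f, numeric(2)))
    tibble::tibble(trial_id = trial_id, participant_id = ids[i], t = t,
                   x = xy[, 1], y = xy[, 2], heading = 0,
                   informed = informed[i])
  }) |> purrr::list_rbind()
}

stationary_fn <- function(x, y) function(t) c(x, y)

# opinion tibble for hand-trace event tests; sites is a character vector
# (NA = no opinion), modes a matching vector
synth_opinions <- function(sites, modes, participant = "P01", trial = "T1") {
  tibble::tibble(trial_id = trial, participant_id = participant,
                 t = seq_along(sites) - 1, site = sites, mode = modes)
}

synth_metrics <- function(opinions, x = 0, y = 0, ds = 0L) {
  tibble::tibble(trial_id = opinions$trial_id,
                 participant_id = opinions$participant_id,
                 t = opinions$t, x = x, y = y, delta_social = ds)
}
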