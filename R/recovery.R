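#' Switch-hazard coefficient recovery study
#'
#' Validation harness for the full measurement-and-inference chain:
#' simulates trials with known hazard coefficients, rebuilds events from the
#' trajectories alone, and refits the event-level logistic models. The
#' moving-switch model (`switch ~ delta_social + distance`) is fitted on
#' global-condition events, the still-switch model
#' (`switch ~ delta_social + time_passed`) on local-condition events,
#' mirroring where each decision mode carries information.
#'
#' @param n_global,n_local Trials to simulate per condition (difficulties
#'   are cycled evenly across trials).
#' @param params An [agent_params()] holding the generating coefficients.
#' @param master_seed Integer seed.
#' @param n_participants Group size.
#' @param nAGQ Integration setting for the binomial fits (0 is fast and
#'   adequate for recovery checks).
#' @param sample_rate Trajectory logging rate (Hz) for the simulated
#'   trials. Decisions are made on the 1 s tick regardless; 5 Hz logging
#'   keeps velocity estimates crisp while halving simulation cost.
#' @return A list: `moving` and `still` (tidied fixed effects of the two
#'   fits, or `NULL` if that condition had no trials), `n_events`,
#'   `estimates` (named vector with `beta_ds`, `beta_dist`, `beta_time`).
#' @export
hazard_recovery <- function(n_global = 150, n_local = 50,
                            params = agent_params(), master_seed = 1,
                            n_participants = 8, nAGQ = 0,
                            sample_rate = 5) {
  difficulties <- c("easy", "medium", "hard")
  seeds <- withr::with_seed(as.integer(master_seed),
                            sample.int(.Machine$integer.max - 1L,
                                       n_global + n_local))
  sim_events <- function(condition, n_trials, seed_offset) {
    if (n_trials == 0) return(empty_events())
    cfgs <- lapply(difficulties, function(d) {
      trial_config(condition = condition, difficulty = d,
                   n_participants = n_participants,
                   sample_rate = sample_rate)
    })
    names(cfgs) <- difficulties
    # pool the trajectories of each difficulty and run the measurement
    # chain once per pool (the chain is multi-trial aware; the trial
    # config is shared within a difficulty)
    purrr::map(difficulties, function(d) {
      idx <- which(difficulties[(seq_len(n_trials) - 1L) %% 3L + 1L] == d)
      if (length(idx) == 0) return(empty_events())
      traj <- purrr::map(idx, function(i) {
        simulate_trial(cfgs[[d]], params, seed = seeds[seed_offset + i],
                       trial_id = sprintf("%s_%04d", condition, i))$trajectories
      }) |> purrr::list_rbind()
      build_events(traj, cfgs[[d]])
    }) |> purrr::list_rbind()
  }
  ev_g <- sim_events("global", n_global, 0L)
  ev_l <- sim_events("local", n_local, n_global)
  est <- c(beta_ds = NA_real_, beta_dist = NA_real_, beta_time = NA_real_)
  moving <- still <- NULL
  mv <- ev_g[ev_g$mode == "moving", ]
  if (nrow(mv) > 0) {
    mv$participant_uid <- paste(mv$trial_id, mv$participant_id)
    fit_mv <- fit_model(mv, switch ~ delta_social + distance,
                        random = "participant_uid", family = "binomial",
                        nAGQ = nAGQ)
    moving <- tidy(fit_mv)
    est["beta_ds"] <- moving$estimate[moving$term == "delta_social"]
    est["beta_dist"] <- moving$estimate[moving$term == "distance"]
  }
  st <- ev_l[ev_l$mode == "still", ]
  if (nrow(st) > 0 && sum(st$switch) > 0) {
    st$participant_uid <- paste(st$trial_id, st$participant_id)
    fit_st <- fit_model(st, switch ~ delta_social + time_passed,
                        random = "participant_uid", family = "binomial",
                        nAGQ = nAGQ)
    still <- tidy(fit_st)
    est["beta_time"] <- still$estimate[still$term == "time_passed"]
  }
  list(moving = moving, still = still,
       n_events = c(moving = nrow(mv), still = nrow(st)),
       estimates = est)
}

#' Type-I error calibration of the Type II Wald test
#'
#' Simulates null datasets (a Gaussian response unrelated to a three-level
#' factor, with a correlated continuous covariate present in the model) and
#' records the rejection rate of the factor's Type II Wald chi-square test
#' at the given alpha.
#'
#' @param n_reps Number of simulated datasets.
#' @param n_obs Observations per dataset.
#' @param alpha Nominal level.
#' @param master_seed Integer seed.
#' @return A list: `rejection_rate`, `n_reps`, `p_values`.
#' @export
wald_type1_calibration <- function(n_reps = 1000, n_obs = 60, alpha = 0.05,
                                   master_seed = 1) {
  pvals <- withr::with_seed(as.integer(master_seed), {
    vapply(seq_len(n_reps), function(i) {
      f <- factor(rep(c("a", "b", "c"), length.out = n_obs))
      x <- stats::rnorm(n_obs)
      y <- 0.5 * x + stats::rnorm(n_obs)  # factor truly null
      fit <- fit_model(tibble::tibble(y = y, x = x, f = f), y ~ x + f,
                       family = "gaussian")
      a <- anova_type2(fit)
      a$p_value[a$term == "f"]
    }, numeric(1))
  })
  list(rejection_rate = mean(pvals < alpha), n_reps = n_reps,
       p_values = pvals)
}
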