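#' Run the full simulate-to-inference pipeline
#'
#' Simulates a design grid, extracts opinions and metrics, builds switch
#' events, scores outcomes, fits the switch-hazard and approach-speed
#' models, and writes every table (CSV), a markdown summary and a JSON
#' manifest to `out_dir`.
#'
#' The fitted models mirror the analysis chain: a binomial mixed model of
#' moving switches on DeltaSocial x difficulty + on_correct (global
#' condition), a binomial mixed model of still switches on time_passed +
#' DeltaSocial + DeltaSocial^2 (local condition), and a linear mixed model
#' of approach speed on COM distance x informed (informed-minority
#' condition).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_per_cell Trials per condition-by-difficulty cell.
#' @param master_seed Master seed for all stochastic stages.
#' @param params An [agent_params()].
#' @param n_participants Group size.
#' @param sample_rate Trajectory logging rate (Hz).
#' @return Invisibly, a list with the outcome summary, the three fits, their
#'   ANOVA tables, the difficulty contrasts and the manifest.
#' @export
run_pipeline <- function(out_dir, n_per_cell = 20, master_seed = 1,
                         params = agent_params(), n_participants = 8,
                         sample_rate = 10) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  batch <- simulate_batch(
    n_per_cell = n_per_cell, params = params, master_seed = master_seed,
    keep_trajectories = TRUE, n_participants = n_participants,
    sample_rate = sample_rate
  )
  events <- purrr::map(unique(batch$trajectories$trial_id), function(id) {
    tr <- batch$trajectories[batch$trajectories$trial_id == id, ]
    cond <- batch$outcomes$condition[batch$outcomes$trial_id == id]
    diff <- batch$outcomes$difficulty[batch$outcomes$trial_id == id]
    build_events(tr, batch$configs[[paste(cond, diff, sep = "_")]])
  }) |> purrr::list_rbind()
  events$participant_uid <- paste(events$trial_id, events$participant_id)
  summary_tbl <- summarize_outcomes(batch$outcomes)
  moving <- events[events$mode == "moving" & events$condition == "global", ]
  still <- events[events$mode == "still" & events$condition == "local", ]
  fit_moving <- fit_model(
    moving, switch ~ delta_social * difficulty + on_correct,
    random = "participant_uid", family = "binomial", nAGQ = 0
  )
  fit_still <- if (nrow(still) > 50 && sum(still$switch) > 5) {
    fit_model(
      still, switch ~ time_passed + delta_social + I(delta_social^2),
      random = "participant_uid", family = "binomial", nAGQ = 0
    )
  }
  traj_inf <- batch$trajectories[
    grepl("^informed_minority", batch$trajectories$trial_id),
  ]
  met <- purrr::map(unique(traj_inf$trial_id), function(id) {
    tr <- traj_inf[traj_inf$trial_id == id, ]
    diff <- batch$outcomes$difficulty[batch$outcomes$trial_id == id]
    cfg <- batch$configs[[paste("informed_minority", diff, sep = "_")]]
    ops <- opinion_series(tr, cfg)
    dplyr::mutate(trial_metrics(resample_1hz(tr), ops, cfg), difficulty = diff)
  }) |> purrr::list_rbind()
  met$participant_uid <- paste(met$trial_id, met$participant_id)
  fit_approach <- fit_model(
    met, approach_speed ~ com_dist * informed * difficulty,
    random = "participant_uid", family = "gaussian"
  )
  anova_moving <- anova_type2(fit_moving)
  anova_approach <- anova_type2(fit_approach)
  contrasts_diff <- emm_pairwise(fit_moving, "difficulty")
  readr::write_csv(batch$outcomes, file.path(out_dir, "outcomes.csv"))
  readr::write_csv(summary_tbl, file.path(out_dir, "outcome_summary.csv"))
  readr::write_csv(events, file.path(out_dir, "events.csv"))
  readr::write_csv(tidy(fit_moving), file.path(out_dir, "fit_moving.csv"))
  if (!is.null(fit_still)) {
    readr::write_csv(tidy(fit_still), file.path(out_dir, "fit_still.csv"))
  }
  readr::write_csv(tidy(fit_approach), file.path(out_dir, "fit_approach.csv"))
  readr::write_csv(anova_moving, file.path(out_dir, "anova_moving.csv"))
  readr::write_csv(anova_approach, file.path(out_dir, "anova_approach.csv"))
  readr::write_csv(contrasts_diff, file.path(out_dir, "contrasts_difficulty.csv"))
  manifest <- list(
    master_seed = master_seed,
    n_per_cell = n_per_cell,
    n_participants = n_participants,
    sample_rate = sample_rate,
    n_trials = nrow(batch$outcomes),
    n_events = nrow(events),
    trial_seeds = stats::setNames(as.list(batch$outcomes$seed),
                                  batch$outcomes$trial_id),
    files = list.files(out_dir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  md <- c(
    "# Pipeline report", "",
    sprintf("%d trials (%d per cell), master seed %d.",
            nrow(batch$outcomes), n_per_cell, master_seed), "",
    "## Success by condition and difficulty", "",
    paste(utils::capture.output(print(as.data.frame(
      summary_tbl[c("condition", "difficulty", "n_trials", "success_prop")]
    ))), collapse = "\n"), "",
    "## Moving-switch model (global)", "",
    paste(utils::capture.output(print(as.data.frame(tidy(fit_moving)))),
          collapse = "\n"), ""
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(list(
    summary = summary_tbl, outcomes = batch$outcomes, events = events,
    fit_moving = fit_moving, fit_still = fit_still,
    fit_approach = fit_approach, anova_moving = anova_moving,
    anova_approach = anova_approach, contrasts_difficulty = contrasts_diff,
    manifest = manifest
  ))
}
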