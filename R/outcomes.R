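#' Detect group consensus in a trajectory table
#'
#' Consensus is the first second (on the 1 Hz grid) at which every
#' participant's position lies strictly inside the same site disc.
#'
#' @param traj A trajectory tibble (resampled internally to 1 Hz).
#' @param config A [trial_config()].
#' @return A list with `site` (label or `NA`) and `time` (seconds or `NA`).
#' @export
detect_consensus <- function(traj, config) {
  t1 <- resample_1hz(traj)
  secs <- sort(unique(t1$t))
  for (s in secs) {
    at <- t1[t1$t == s, ]
    occ <- occupied_site(at$x, at$y, config)
    if (length(occ) == config$n_participants && !anyNA(occ) &&
        length(unique(occ)) == 1) {
      return(list(site = occ[1], time = s))
    }
  }
  list(site = NA_character_, time = NA_real_)
}

#' Score a trial outcome
#'
#' Maps a consensus (site, time) to the trial outcome: correct consensus
#' earns `100 - time` gold points, an incorrect consensus or no consensus
#' earns none.
#'
#' @param site Consensus site label or `NA`.
#' @param time Consensus time in seconds or `NA`.
#' @param config A [trial_config()].
#' @param trial_id Label recorded in the output.
#' @return A one-row tibble: `trial_id, condition, difficulty,
#'   n_participants, consensus_site, consensus_time, outcome, success, gold`.
#' @export
#' @examples
#' cfg <- trial_config("global", "easy", correct_site = "B")
#' score_trial("B", 36, cfg) # success, 64 gold
score_trial <- function(site, time, config, trial_id = "trial1") {
  if (!is.na(site) && (is.na(time) || time > config$time_limit)) {
    stop("consensus time must lie within the time limit", call. = FALSE)
  }
  outcome <- if (is.na(site)) {
    "no_consensus"
  } else if (site == config$correct_site) {
    "correct_consensus"
  } else {
    "incorrect_consensus"
  }
  success <- as.integer(outcome == "correct_consensus")
  tibble::tibble(
    trial_id = trial_id,
    condition = config$condition,
    difficulty = config$difficulty,
    n_participants = config$n_participants,
    consensus_site = site,
    consensus_time = time,
    outcome = outcome,
    success = success,
    gold = if (success == 1) 100 - time else 0
  )
}

#' Wilson 95% confidence interval for a proportion
#'
#' @param k Number of successes. @param n Number of trials.
#' @param conf Confidence level.
#' @return A named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Summarise trial outcomes by condition and difficulty
#'
#' Per design cell: the success proportion with its 95% Wilson interval, the
#' mean and SD of the consensus time over successful trials, and the mean
#' consensus time of incorrect-consensus trials.
#'
#' @param outcomes An outcome tibble (rows from [score_trial()], e.g.
#'   `simulate_batch()$outcomes`).
#' @return A tibble of class `arena_summary`, one row per
#'   condition-by-difficulty cell.
#' @export
summarize_outcomes <- function(outcomes) {
  out <- outcomes |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_consensus = sum(.data$outcome != "no_consensus"),
      n_success = sum(.data$success),
      success_prop = mean(.data$success),
      success_lo = wilson_ci(sum(.data$success), dplyr::n())[["lower"]],
      success_hi = wilson_ci(sum(.data$success), dplyr::n())[["upper"]],
      time_success_mean = mean(.data$consensus_time[.data$success == 1]),
      time_success_sd = stats::sd(.data$consensus_time[.data$success == 1]),
      time_incorrect_mean = mean(.data$consensus_time[.data$outcome ==
                                                        "incorrect_consensus"]),
      mean_gold = mean(.data$gold),
      .by = c("condition", "difficulty")
    )
  class(out) <- c("arena_summary", class(out))
  out
}
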