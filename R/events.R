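# one record per qualifying participant-second; the "sustained for at least
# one second" rule and the occupation clock are computed with grouped
# lead/lag vector operations
scan_events <- function(series, metrics, config, which_mode) {
  s <- series |>
    dplyr::arrange(.data$trial_id, .data$participant_id, .data$t) |>
    dplyr::group_by(.data$trial_id, .data$participant_id) |>
    dplyr::mutate(
      lead_site = dplyr::lead(.data$site),
      lead_mode = dplyr::lead(.data$mode),
      lead2_site = dplyr::lead(.data$site, 2),
      is_last = dplyr::row_number() == dplyr::n(),
      occ = .data$mode == "occupying",
      # an occupation run starts unless the previous bin was the same site,
      # occupying, exactly one second earlier
      occ_run_start = .data$occ & !(
        dplyr::row_number() > 1 &
          dplyr::coalesce(dplyr::lag(.data$mode) == "occupying", FALSE) &
          dplyr::coalesce(dplyr::lag(.data$site) == .data$site, FALSE) &
          dplyr::coalesce(abs(.data$t - dplyr::lag(.data$t) - 1) < 1e-9, FALSE)
      ),
      occ_start = cummax(ifelse(.data$occ_run_start, .data$t, -Inf)),
      # a sustained switch: the next bin supports a different site while
      # moving, and that support holds for a further bin
      sustained = !is.na(.data$site) & !is.na(.data$lead_site) &
        .data$lead_site != .data$site &
        .data$lead_mode == "moving_toward" &
        !is.na(.data$lead2_site) & .data$lead2_site == .data$lead_site
    ) |>
    dplyr::ungroup()
  keep <- if (which_mode == "moving") {
    !is.na(s$site) & s$mode == "moving_toward" & !s$is_last
  } else {
    s$occ & !s$is_last & s$t > s$occ_start
  }
  s <- s[keep, ]
  if (nrow(s) == 0) return(empty_events())
  out <- tibble::tibble(
    trial_id = s$trial_id,
    participant_id = s$participant_id,
    t = s$t,
    mode = if (which_mode == "moving") "moving" else "still",
    switch = as.integer(s$sustained),
    on_correct = as.integer(s$site == config$correct_site),
    condition = config$condition,
    difficulty = config$difficulty,
    group_id = s$trial_id,
    group_size = config$n_participants,
    avatar_type = "bulldozer"
  )
  met <- metrics[c("trial_id", "participant_id", "t", "x", "y", "delta_social")]
  out <- dplyr::left_join(out, met,
                          by = c("trial_id", "participant_id", "t"))
  if (which_mode == "moving") {
    k <- match(s$site, config$sites$id)
    out$distance <- sqrt((out$x - config$sites$x[k])^2 +
                           (out$y - config$sites$y[k])^2)
    out$time_passed <- NA_real_
  } else {
    out$distance <- NA_real_
    out$time_passed <- s$t - s$occ_start
  }
  out[c("trial_id", "participant_id", "t", "mode", "switch", "on_correct",
        "delta_social", "distance", "time_passed", "condition", "difficulty",
        "group_id", "group_size", "avatar_type")] |>
    dplyr::arrange(.data$trial_id, .data$participant_id, .data$t)
}

empty_events <- function() {
  tibble::tibble(
    trial_id = character(), participant_id = character(), t = numeric(),
    mode = character(), switch = integer(), on_correct = integer(),
    delta_social = integer(), distance = numeric(), time_passed = numeric(),
    condition = character(), difficulty = character(), group_id = character(),
    group_size = integer(), avatar_type = character()
  )
}

#' Per-second switch events while moving towards a site
#'
#' Every second during which a participant is moving towards a candidate
#' site and keeps supporting it in the next second is a `switch = 0` sample;
#' if in the next second the participant instead supports an alternative
#' site and sustains that support for at least one further second, the
#' current second becomes a `switch = 1` sample. Seconds with no opinion and
#' the terminal second of each series (which has no successor) emit nothing.
#' Covariates (DeltaSocial, distance to the current target's center,
#' OnCorrect) are evaluated at the bin start.
#'
#' @param series An opinion tibble from [opinion_series()].
#' @param metrics The matching metrics tibble from [trial_metrics()].
#' @param config A [trial_config()].
#' @return An event tibble with columns `trial_id, participant_id, t, mode,
#'   switch, on_correct, delta_social, distance, time_passed, condition,
#'   difficulty, group_id, group_size, avatar_type`.
#' @export
build_moving_events <- function(series, metrics, config) {
  scan_events(series, metrics, config, "moving")
}

#' Per-second switch events while occupying a site
#'
#' As [build_moving_events()], but for seconds spent occupying a candidate
#' site. `time_passed` is the number of seconds since the current occupation
#' began; the first second of an occupation initializes the clock and emits
#' no sample, and the clock resets whenever occupation is interrupted.
#' A departure counts as a switch only if the participant starts moving
#' towards an alternative site and sustains it for at least one second.
#'
#' @inheritParams build_moving_events
#' @return An event tibble (see [build_moving_events()]).
#' @export
build_still_events <- function(series, metrics, config) {
  scan_events(series, metrics, config, "still")
}

#' Merge moving and still event tables
#'
#' @param moving,still Event tibbles.
#' @return The concatenated tibble ordered by (trial, participant, t);
#'   duplicated `(trial_id, participant_id, t, mode)` keys are an error.
#' @export
merge_events <- function(moving, still) {
  out <- dplyr::bind_rows(moving, still)
  key <- paste(out$trial_id, out$participant_id, out$t, out$mode)
  if (anyDuplicated(key)) {
    stop("duplicate event keys: ", key[which(duplicated(key))[1]], call. = FALSE)
  }
  dplyr::arrange(out, .data$trial_id, .data$participant_id, .data$t)
}

#' Full event table for one simulated or recorded trial table
#'
#' Convenience wrapper running [resample_1hz()], [opinion_series()],
#' [trial_metrics()] and both event builders.
#'
#' @param traj A trajectory tibble (raw rate).
#' @param config A [trial_config()].
#' @return The merged event tibble.
#' @export
build_events <- function(traj, config) {
  t1 <- resample_1hz(traj)
  ops <- opinion_series(traj, config)
  met <- trial_metrics(t1, ops, config)
  merge_events(build_moving_events(ops, met, config),
               build_still_events(ops, met, config))
}
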