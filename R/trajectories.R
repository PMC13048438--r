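#' Validate a trajectory table against a trial configuration
#'
#' Checks the invariants every downstream stage relies on: required columns,
#' non-negative strictly increasing timestamps per participant, positions
#' within the arena bounds, no duplicated (participant, t) pairs, and a
#' participant set matching the configuration.
#'
#' @param traj A trajectory tibble with columns
#'   `trial_id, participant_id, t, x, y, heading, informed`.
#' @param config A [trial_config()].
#' @return `traj` invisibly (errors describe the offending rows).
#' @export
validate_trajectories <- function(traj, config) {
  required <- c("trial_id", "participant_id", "t", "x", "y", "heading", "informed")
  missing <- setdiff(required, names(traj))
  if (length(missing)) {
    stop("trajectory table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(traj$t < 0)) stop("negative timestamps found", call. = FALSE)
  dup <- duplicated(traj[c("trial_id", "participant_id", "t")])
  if (any(dup)) {
    bad <- traj[which(dup)[1], ]
    stop(sprintf("duplicated (participant, t) pair: %s, %s, t = %g",
                 bad$trial_id, bad$participant_id, bad$t), call. = FALSE)
  }
  oob <- abs(traj$x) > config$arena_half_extent | abs(traj$y) > config$arena_half_extent
  if (any(oob)) {
    bad <- traj[which(oob)[1], ]
    stop(sprintf(
      "position outside arena bounds (half-extent %g m): %s, %s, t = %g, (%g, %g)",
      config$arena_half_extent, bad$trial_id, bad$participant_id, bad$t, bad$x, bad$y
    ), call. = FALSE)
  }
  by_pt <- split(traj$t, interaction(traj$trial_id, traj$participant_id, drop = TRUE))
  nondec <- vapply(by_pt, function(tt) all(diff(tt) > 0), logical(1))
  if (!all(nondec)) {
    stop("timestamps not strictly increasing for participant ",
         names(by_pt)[which(!nondec)[1]], call. = FALSE)
  }
  for (trial in unique(traj$trial_id)) {
    ids <- unique(traj$participant_id[traj$trial_id == trial])
    if (!setequal(ids, config$participants)) {
      stop(sprintf("trial %s has participants {%s}; config expects {%s}",
                   trial, paste(sort(ids), collapse = ","),
                   paste(config$participants, collapse = ",")), call. = FALSE)
    }
  }
  invisible(traj)
}

#' Read and write trajectory tables
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `trial_id,participant_id,t,x,y,heading,informed`, `.` decimal separator
#' and one frame per row. `read_trajectories()` validates against `config`.
#'
#' @param traj A trajectory tibble.
#' @param path File path.
#' @param config A [trial_config()] used for validation.
#' @return `read_trajectories()` returns the validated tibble;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  cols <- c("trial_id", "participant_id", "t", "x", "y", "heading", "informed")
  out <- traj[cols]
  for (v in c("t", "x", "y", "heading")) {
    out[[v]] <- fmt_roundtrip(out[[v]])
  }
  out$informed <- ifelse(out$informed, "TRUE", "FALSE")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# shortest decimal string that parses back to exactly the same double, so
# that write -> read -> write is bit-identical
fmt_roundtrip <- function(x) {
  s <- sprintf("%.15g", x)
  for (digits in c("%.16g", "%.17g")) {
    bad <- as.numeric(s) != x
    if (!any(bad)) break
    s[bad] <- sprintf(digits, x[bad])
  }
  s
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, config) {
  traj <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial_id = readr::col_character(),
      participant_id = readr::col_character(),
      t = readr::col_character(),
      x = readr::col_character(),
      y = readr::col_character(),
      heading = readr::col_character(),
      informed = readr::col_logical()
    ),
    progress = FALSE
  )
  # correctly-rounded decimal -> double conversion (strtod), so that the
  # write -> load round trip is exact to the last ulp
  for (v in c("t", "x", "y", "heading")) {
    parsed <- as.numeric(traj[[v]])
    if (anyNA(parsed) && !all(is.na(traj[[v]][is.na(parsed)]))) {
      stop("non-numeric value in column ", v, call. = FALSE)
    }
    traj[[v]] <- parsed
  }
  validate_trajectories(traj, config)
  traj
}

#' Finite-difference velocities
#'
#' Adds `vx`, `vy` columns: central differences of position at interior
#' timestamps, one-sided differences at the series ends. Participants with a
#' single frame raise an error (no derivative exists).
#'
#' @param traj A trajectory tibble.
#' @return The tibble with `vx` and `vy` appended.
#' @export
add_velocity <- function(traj) {
  sizes <- dplyr::count(traj, .data$trial_id, .data$participant_id)
  if (any(sizes$n < 2)) {
    bad <- sizes[sizes$n < 2, ][1, ]
    stop(sprintf("participant %s has a single frame; velocity undefined",
                 bad$participant_id), call. = FALSE)
  }
  traj |>
    dplyr::arrange(.data$trial_id, .data$participant_id, .data$t) |>
    dplyr::group_by(.data$trial_id, .data$participant_id) |>
    dplyr::mutate(
      vx = (dplyr::coalesce(dplyr::lead(.data$x), .data$x) -
              dplyr::coalesce(dplyr::lag(.data$x), .data$x)) /
        (dplyr::coalesce(dplyr::lead(.data$t), .data$t) -
           dplyr::coalesce(dplyr::lag(.data$t), .data$t)),
      vy = (dplyr::coalesce(dplyr::lead(.data$y), .data$y) -
              dplyr::coalesce(dplyr::lag(.data$y), .data$y)) /
        (dplyr::coalesce(dplyr::lead(.data$t), .data$t) -
           dplyr::coalesce(dplyr::lag(.data$t), .data$t))
    ) |>
    dplyr::ungroup()
}

#' Velocity of one participant at one timestamp
#'
#' @param traj A trajectory tibble.
#' @param participant Participant label.
#' @param t Timestamp (must exist in the participant's series).
#' @return A length-2 numeric vector `(vx, vy)` in m/s.
#' @export
velocity_at <- function(traj, participant, t) {
  sub <- traj[traj$participant_id == participant, ]
  if (nrow(sub) == 0) stop("unknown participant: ", participant, call. = FALSE)
  if (!any(abs(sub$t - t) < 1e-9)) {
    stop(sprintf("t = %g is not a timestamp of participant %s", t, participant),
         call. = FALSE)
  }
  v <- add_velocity(sub)
  row <- v[abs(v$t - t) < 1e-9, ]
  c(vx = row$vx[1], vy = row$vy[1])
}

#' Resample a trajectory table to the 1 Hz analysis grid
#'
#' Keeps, for every participant and every integer second covered by the
#' recording, the bin-start sample: the first frame with `t` in `[s, s + 1)`.
#' The kept frame's timestamp is snapped to the integer `s`. Applying the
#' function twice is a no-op.
#'
#' @param traj A trajectory tibble.
#' @return A trajectory tibble with one frame per participant per second.
#' @export
resample_1hz <- function(traj) {
  if (nrow(traj) == 0) stop("empty trajectory table", call. = FALSE)
  traj |>
    dplyr::arrange(.data$trial_id, .data$participant_id, .data$t) |>
    dplyr::mutate(..sec = floor(.data$t + 1e-9)) |>
    dplyr::distinct(.data$trial_id, .data$participant_id, .data$..sec,
                    .keep_all = TRUE) |>
    dplyr::mutate(t = .data$..sec) |>
    dplyr::select(-"..sec")
}
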