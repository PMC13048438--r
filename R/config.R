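#' Candidate-site geometry for a trial
#'
#' Builds the four circular candidate sites of the standard arena: centers at
#' (+/-40, +/-40) m, incorrect sites with a 12 m radius and the correct site
#' enlarged according to the difficulty level (easy 15 m, medium 14 m,
#' hard 13 m).
#'
#' @param difficulty One of `"easy"`, `"medium"`, `"hard"`.
#' @param correct_site Label of the correct (largest) site, one of
#'   `"A"`,`"B"`,`"C"`,`"D"`. Site A is at (-40,-40), B at (-40,40),
#'   C at (40,-40), D at (40,40).
#' @param base_radius Radius of the incorrect sites in meters.
#'
#' @return A tibble with columns `id`, `x`, `y`, `radius` (one row per site).
#' @export
#' @examples
#' arena_sites("easy", "D")
arena_sites <- function(difficulty = c("easy", "medium", "hard"),
                        correct_site = "D",
                        base_radius = 12) {
  difficulty <- match.arg(difficulty)
  correct_site <- match.arg(correct_site, c("A", "B", "C", "D"))
  r_correct <- correct_radius(difficulty, base_radius)
  sites <- tibble::tibble(
    id = c("A", "B", "C", "D"),
    x = c(-40, -40, 40, 40),
    y = c(-40, 40, -40, 40),
    radius = base_radius
  )
  sites$radius[sites$id == correct_site] <- r_correct
  sites
}

correct_radius <- function(difficulty, base_radius = 12) {
  base_radius + switch(difficulty, easy = 3, medium = 2, hard = 1)
}

#' Relative radius excess of the correct site
#'
#' How much larger (in percent) the correct site's radius is than the
#' incorrect sites' 12 m radius: 25% (easy), 16.7% (medium), 8.3% (hard).
#'
#' @param difficulty One of `"easy"`, `"medium"`, `"hard"` (vectorised).
#' @param base_radius Radius of the incorrect sites in meters.
#' @return Percentage excess, numeric.
#' @export
#' @examples
#' radius_excess(c("easy", "hard"))
radius_excess <- function(difficulty, base_radius = 12) {
  stopifnot(all(difficulty %in% c("easy", "medium", "hard")))
  r <- vapply(difficulty, correct_radius, numeric(1), base_radius = base_radius)
  unname(100 * (r - base_radius) / base_radius)
}

#' Session bookkeeping totals
#'
#' Totals for an experiment made of sessions with varying group sizes.
#' The default corresponds to the reference design: 9 sessions of 7
#' participants, 11 of 8, 8 of 9 and 4 of 10.
#'
#' @param sessions A data frame with columns `group_size` and `n_sessions`.
#' @return A one-row tibble with `n_sessions` and `n_participants`.
#' @export
#' @examples
#' session_totals()
session_totals <- function(sessions = tibble::tibble(
                             group_size = c(7, 8, 9, 10),
                             n_sessions = c(9, 11, 8, 4)
                           )) {
  stopifnot(all(c("group_size", "n_sessions") %in% names(sessions)))
  tibble::tibble(
    n_sessions = sum(sessions$n_sessions),
    n_participants = sum(sessions$group_size * sessions$n_sessions)
  )
}

#' Trial configuration
#'
#' Assembles and validates the full configuration of a single trial: arena
#' geometry, candidate sites, experimental condition and difficulty, group
#' composition and kinematic constants.
#'
#' @param condition One of `"global"` (site sizes visible from anywhere),
#'   `"local"` (sizes only visible within `local_visibility_radius`), or
#'   `"informed_minority"` (global visibility plus two participants told the
#'   correct site).
#' @param difficulty One of `"easy"`, `"medium"`, `"hard"`.
#' @param n_participants Group size, an integer between 7 and 10.
#' @param correct_site Label of the correct site.
#' @param informed_ids Participant labels of the informed individuals.
#'   Defaults to the first two participants in the informed-minority
#'   condition and none otherwise.
#' @param speed Forward speed in m/s.
#' @param rot_rate Maximum rotation rate in rad/s.
#' @param time_limit Trial time limit in seconds.
#' @param sample_rate Trajectory logging rate in Hz.
#' @param local_visibility_radius Distance (m) within which a site's size is
#'   revealed in the local condition.
#' @param start_radius Participants start uniformly within this distance (m)
#'   of the arena center.
#' @param arena_half_extent Half the side of the square arena, in meters.
#' @param base_radius Radius of the incorrect sites in meters.
#'
#' @return An object of class `trial_config` (a named list; `$sites` is the
#'   tibble from [arena_sites()]).
#' @export
#' @examples
#' cfg <- trial_config("global", "easy", n_participants = 8)
#' cfg$sites
trial_config <- function(condition = c("global", "local", "informed_minority"),
                         difficulty = c("easy", "medium", "hard"),
                         n_participants = 10,
                         correct_site = "D",
                         informed_ids = NULL,
                         speed = 8,
                         rot_rate = pi,
                         time_limit = 100,
                         sample_rate = 10,
                         local_visibility_radius = 25,
                         start_radius = 20,
                         arena_half_extent = 75,
                         base_radius = 12) {
  condition <- match.arg(condition)
  difficulty <- match.arg(difficulty)
  if (!is.numeric(n_participants) || n_participants < 7 || n_participants > 10 ||
      n_participants != round(n_participants)) {
    stop("`n_participants` must be an integer between 7 and 10", call. = FALSE)
  }
  n_participants <- as.integer(n_participants)
  participants <- sprintf("P%02d", seq_len(n_participants))
  if (is.null(informed_ids)) {
    informed_ids <- if (condition == "informed_minority") participants[1:2] else character()
  }
  if (condition == "informed_minority" && length(informed_ids) != 2) {
    stop("informed_minority trials have exactly 2 informed participants", call. = FALSE)
  }
  if (condition != "informed_minority" && length(informed_ids) > 0) {
    stop("only informed_minority trials have informed participants", call. = FALSE)
  }
  if (!all(informed_ids %in% participants)) {
    stop("`informed_ids` must be a subset of the participant labels", call. = FALSE)
  }
  sites <- arena_sites(difficulty, correct_site, base_radius)
  if (any(abs(sites$x) + sites$radius > arena_half_extent |
          abs(sites$y) + sites$radius > arena_half_extent)) {
    stop("sites must lie inside the arena", call. = FALSE)
  }
  stopifnot(speed > 0, rot_rate > 0, time_limit > 0, sample_rate >= 1,
            start_radius > 0, local_visibility_radius > 0)
  structure(
    list(
      condition = condition,
      difficulty = difficulty,
      n_participants = n_participants,
      participants = participants,
      correct_site = correct_site,
      informed_ids = informed_ids,
      sites = sites,
      speed = speed,
      rot_rate = rot_rate,
      time_limit = time_limit,
      sample_rate = sample_rate,
      local_visibility_radius = local_visibility_radius,
      start_radius = start_radius,
      arena_half_extent = arena_half_extent,
      base_radius = base_radius
    ),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config> ", x$condition, "/", x$difficulty,
      ", N = ", x$n_participants, ", correct site ", x$correct_site,
      " (r = ", x$sites$radius[x$sites$id == x$correct_site], " m)\n", sep = "")
  if (length(x$informed_ids)) {
    cat("  informed: ", paste(x$informed_ids, collapse = ", "), "\n", sep = "")
  }
  cat("  speed ", x$speed, " m/s, rot ", signif(x$rot_rate, 4),
      " rad/s, limit ", x$time_limit, " s, ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Read / write a trial configuration as YAML
#'
#' @param config A `trial_config` object.
#' @param path File path.
#' @return `read_config()` returns a `trial_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  fields <- config[c("condition", "difficulty", "n_participants", "correct_site",
                     "informed_ids", "speed", "rot_rate", "time_limit",
                     "sample_rate", "local_visibility_radius", "start_radius",
                     "arena_half_extent", "base_radius")]
  fields$informed_ids <- as.list(fields$informed_ids)
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  fields <- yaml::read_yaml(path)
  fields$informed_ids <- as.character(unlist(fields$informed_ids))
  if (length(fields$informed_ids) == 0) fields$informed_ids <- NULL
  do.call(trial_config, fields)
}

site_lookup <- function(config, id) {
  k <- match(id, config$sites$id)
  list(id = id, x = config$sites$x[k], y = config$sites$y[k],
       radius = config$sites$radius[k])
}
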