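#' Disagreeing social information (DeltaSocial)
#'
#' The difference between the largest number of other individuals supporting
#' any one of the unselected options and the number of other individuals
#' supporting the focal's current selection. Positive values mean the
#' persuasive force towards an alternative exceeds the support for the
#' current choice; the range is `[-(N-1), N-1]` for a group of size N.
#' The focal individual is excluded from all counts.
#'
#' @param counts Named length-4 integer vector of supporter counts over the
#'   *other* individuals (names `A, B, C, D`; absent names count as 0).
#' @param current The focal's currently supported site label.
#' @return An integer.
#' @export
#' @examples
#' delta_social(c(A = 2, B = 4, C = 1, D = 0), "A") # 4 - 2 = 2
delta_social <- function(counts, current) {
  if (is.na(current) || !current %in% SITES) {
    stop("focal has no current opinion; DeltaSocial undefined", call. = FALSE)
  }
  full <- stats::setNames(rep(0L, 4), SITES)
  full[names(counts)] <- as.integer(counts)
  max(full[SITES != current]) - full[[current]]
}

#' Per-second DeltaSocial for every participant
#'
#' Joins each opinion record with the supporter counts of the other group
#' members at the same second and computes [delta_social()]. Seconds at which
#' the focal supports no site get `NA`.
#'
#' @param opinions An opinion tibble from [opinion_series()].
#' @return `opinions` with a `delta_social` column appended.
#' @export
add_delta_social <- function(opinions) {
  opinions |>
    dplyr::group_by(.data$trial_id, .data$t) |>
    dplyr::mutate(delta_social = {
      supp <- .data$site
      n_site <- vapply(SITES, function(s) sum(supp == s, na.rm = TRUE), integer(1))
      vapply(seq_along(supp), function(i) {
        if (is.na(supp[i])) return(NA_integer_)
        own <- n_site
        own[supp[i]] <- own[supp[i]] - 1L
        as.integer(delta_social(own, supp[i]))
      }, integer(1))
    }) |>
    dplyr::ungroup()
}

#' Average inter-player distance
#'
#' Mean of all N(N-1)/2 pairwise Euclidean distances at one instant.
#'
#' @param x,y Coordinate vectors of the N participants (m).
#' @return Meters.
#' @export
interplayer_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 participants", call. = FALSE)
  mean(stats::dist(cbind(x, y)))
}

#' Average distance of participants to a site
#'
#' @param x,y Coordinate vectors of the N participants (m).
#' @param site A single site: one row of the tibble from [arena_sites()],
#'   or any list with `x` and `y` elements.
#' @return Meters.
#' @export
mean_distance_to_site <- function(x, y, site) {
  mean(sqrt((x - site$x[1])^2 + (y - site$y[1])^2))
}

group_com <- function(traj) {
  traj |>
    dplyr::summarise(com_x = mean(.data$x), com_y = mean(.data$y),
                     .by = c("trial_id", "t"))
}

#' Distance to the group's center of mass
#'
#' The COM at time t is the unweighted mean position of all N participants,
#' the focal included.
#'
#' @param traj A trajectory tibble (any sample rate; all participants must
#'   share timestamps).
#' @param participant Focal participant label.
#' @param t Timestamp.
#' @return Meters.
#' @export
com_distance <- function(traj, participant, t) {
  at <- traj[abs(traj$t - t) < 1e-9, ]
  if (nrow(at) == 0) stop("t = ", t, " not in the table", call. = FALSE)
  me <- at[at$participant_id == participant, ]
  if (nrow(me) != 1) stop("unknown participant: ", participant, call. = FALSE)
  sqrt((me$x - mean(at$x))^2 + (me$y - mean(at$y))^2)
}

#' Approach speed towards the group's center of mass
#'
#' The negative time derivative of the focal's distance to the COM,
#' multiplied by the norm of the focal's velocity so that only the focal's
#' own movement (not drift of the COM) registers. Positive values mean
#' active approach; units are m^2/s^2. The derivative is a symmetric finite
#' difference spanning `window` seconds (snapped to the table's sampling
#' grid), the velocity a central difference.
#'
#' @param traj A trajectory tibble.
#' @param participant Focal participant label.
#' @param t Timestamp (must admit the symmetric window).
#' @param window Width (s) of the differentiation window.
#' @return Approach speed in m^2/s^2.
#' @export
approach_speed <- function(traj, participant, t, window = 1) {
  sub <- traj[traj$participant_id == participant, ]
  ts <- sort(unique(sub$t))
  if (length(ts) < 3) stop("series too short for a symmetric window", call. = FALSE)
  dt <- min(diff(ts))
  h <- max(dt, round(window / 2 / dt) * dt)
  tm <- t - h; tp <- t + h
  have <- function(tt) any(abs(ts - tt) < 1e-9)
  if (!have(t) || !have(tm) || !have(tp)) {
    stop(sprintf("window [%g, %g] not inside the series", tm, tp), call. = FALSE)
  }
  com <- group_com(traj)
  dist_at <- function(tt) {
    me <- sub[abs(sub$t - tt) < 1e-9, ]
    cc <- com[abs(com$t - tt) < 1e-9, ]
    sqrt((me$x - cc$com_x)^2 + (me$y - cc$com_y)^2)
  }
  pos_at <- function(tt) {
    me <- sub[abs(sub$t - tt) < 1e-9, ]
    c(me$x, me$y)
  }
  ddist <- (dist_at(tp) - dist_at(tm)) / (tp - tm)
  vel <- (pos_at(tp) - pos_at(tm)) / (tp - tm)
  sqrt(sum(vel^2)) * (-ddist)
}

#' Per-second social and spatial metrics table
#'
#' Evaluates, at every bin-start second of a 1 Hz trajectory table, the
#' focal's DeltaSocial, distance to the COM, approach speed towards the COM
#' and the group's mean inter-player distance.
#'
#' @param traj1hz A 1 Hz trajectory tibble ([resample_1hz()]).
#' @param opinions The matching opinion tibble ([opinion_series()]).
#' @param config A [trial_config()].
#' @return A tibble `trial_id, participant_id, t, x, y, informed,
#'   delta_social, com_dist, approach_speed, interplayer_dist` (approach
#'   speed is `NA` at the series ends where the symmetric window does not
#'   fit).
#' @export
trial_metrics <- function(traj1hz, opinions, config) {
  com <- group_com(traj1hz)
  ipd <- traj1hz |>
    dplyr::summarise(interplayer_dist = interplayer_distance(.data$x, .data$y),
                     .by = c("trial_id", "t"))
  ds <- add_delta_social(opinions)
  out <- traj1hz |>
    dplyr::left_join(com, by = c("trial_id", "t")) |>
    dplyr::left_join(ipd, by = c("trial_id", "t")) |>
    dplyr::left_join(
      ds[c("trial_id", "participant_id", "t", "delta_social")],
      by = c("trial_id", "participant_id", "t")
    ) |>
    dplyr::mutate(com_dist = sqrt((.data$x - .data$com_x)^2 +
                                    (.data$y - .data$com_y)^2)) |>
    dplyr::group_by(.data$trial_id, .data$participant_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(approach_speed = {
      n <- dplyr::n()
      if (n < 3) rep(NA_real_, n) else {
        ip <- pmin(seq_len(n) + 1L, n)
        im <- pmax(seq_len(n) - 1L, 1L)
        span <- .data$t[ip] - .data$t[im]
        vx <- (.data$x[ip] - .data$x[im]) / span
        vy <- (.data$y[ip] - .data$y[im]) / span
        dd <- (.data$com_dist[ip] - .data$com_dist[im]) / span
        as_sp <- sqrt(vx^2 + vy^2) * (-dd)
        as_sp[c(1L, n)] <- NA_real_
        as_sp
      }
    }) |>
    dplyr::ungroup()
  out[c("trial_id", "participant_id", "t", "x", "y", "informed",
        "delta_social", "com_dist", "approach_speed", "interplayer_dist")]
}
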