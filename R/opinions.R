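#' Classify a single frame into a movement-based opinion
#'
#' A participant supports a site if moving towards it (speed above
#' `speed_eps` and the angle between the velocity vector and the line from
#' the participant to the site center below `angle_max`; the smallest angle
#' wins, with the nearer site breaking exact ties) or occupying it
#' (speed at most `speed_eps` and position strictly inside exactly one site
#' disc). Otherwise the opinion is none.
#'
#' @param x,y Position (m).
#' @param vx,vy Velocity (m/s).
#' @param sites A site tibble from [arena_sites()] (columns
#'   `id, x, y, radius`).
#' @param angle_max Maximum heading-to-site angle, degrees.
#' @param speed_eps Speed threshold (m/s) separating moving from stationary.
#' @return A list with `site` (label or `NA`) and `mode`
#'   (`"moving_toward"`, `"occupying"` or `"none"`).
#' @export
#' @examples
#' s <- arena_sites("easy", "D")
#' classify_frame(0, 0, 8 / sqrt(2), 8 / sqrt(2), s) # aimed at D
classify_frame <- function(x, y, vx, vy, sites, angle_max = 30, speed_eps = 0.1) {
  cls <- classify_frames(x, y, vx, vy, sites, angle_max, speed_eps)
  list(site = cls$site[1], mode = cls$mode[1])
}

# vectorised classification over frames; one matrix operation per site
classify_frames <- function(x, y, vx, vy, sites, angle_max = 30,
                            speed_eps = 0.1) {
  n <- length(x)
  k <- nrow(sites)
  speed <- sqrt(vx^2 + vy^2)
  dx <- matrix(sites$x, n, k, byrow = TRUE) - x
  dy <- matrix(sites$y, n, k, byrow = TRUE) - y
  dist <- sqrt(dx^2 + dy^2)
  cosang <- (vx * dx + vy * dy) / (speed * dist)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  # smallest angle wins; an infinitesimal distance term breaks exact ties
  # in favour of the nearer site
  score <- ang + dist * 1e-9
  score[ang >= angle_max | dist == 0] <- Inf
  best <- max.col(-score, ties.method = "first")
  best_ok <- is.finite(score[cbind(seq_len(n), best)])
  inside <- dist < matrix(sites$radius, n, k, byrow = TRUE)
  n_inside <- rowSums(inside)
  only <- max.col(inside, ties.method = "first")
  site <- rep(NA_character_, n)
  mode <- rep("none", n)
  moving <- speed > speed_eps
  sel_m <- moving & best_ok
  site[sel_m] <- sites$id[best[sel_m]]
  mode[sel_m] <- "moving_toward"
  sel_o <- !moving & n_inside == 1
  site[sel_o] <- sites$id[only[sel_o]]
  mode[sel_o] <- "occupying"
  list(site = site, mode = mode)
}

#' Opinion time series of every participant
#'
#' Applies the frame classifier (see [classify_frame()]) at each bin-start
#' frame of the 1 Hz analysis grid. Velocities are estimated by finite
#' differences at the table's native sampling rate *before* the grid is
#' thinned to bin starts, so that the brief stop-and-turn around an opinion
#' switch is not smeared across two-second windows (passing an already 1 Hz
#' table falls back to 1 Hz differences).
#'
#' @param traj A trajectory tibble at any sample rate.
#' @param config A [trial_config()].
#' @param angle_max,speed_eps Passed to [classify_frame()].
#' @return A tibble `trial_id, participant_id, t, site, mode` with one row
#'   per participant per second.
#' @export
opinion_series <- function(traj, config, angle_max = 30, speed_eps = 0.1) {
  if (nrow(traj) == 0) stop("empty trajectory table", call. = FALSE)
  v <- add_velocity(traj) |>
    dplyr::mutate(..sec = floor(.data$t + 1e-9)) |>
    dplyr::distinct(.data$trial_id, .data$participant_id, .data$..sec,
                    .keep_all = TRUE) |>
    dplyr::mutate(t = .data$..sec) |>
    dplyr::select(-"..sec")
  cls <- classify_frames(v$x, v$y, v$vx, v$vy, config$sites,
                         angle_max, speed_eps)
  tibble::tibble(
    trial_id = v$trial_id,
    participant_id = v$participant_id,
    t = v$t,
    site = cls$site,
    mode = cls$mode
  ) |>
    dplyr::arrange(.data$trial_id, .data$participant_id, .data$t)
}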