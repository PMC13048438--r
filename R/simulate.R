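#' Behavioural parameters of simulated participants
#'
#' The simulator's decision policy has three ingredients: noisy perception of
#' site radii, social copying when choosing a target, and a per-second
#' logistic switch hazard driven by disagreeing social information
#' (DeltaSocial), distance to the current target and time already spent
#' occupying a site. Defaults are the package's calibration of a plausible
#' participant; see the methods vignette for the rationale.
#'
#' @param sigma_percept SD (m) of the once-per-trial Gaussian error on each
#'   perceived site radius.
#' @param w_social Copying weight (m per supporter) added to a site's
#'   perceived radius during target selection.
#' @param beta_ds Switch-hazard log-odds slope per unit DeltaSocial.
#' @param beta_dist Slope per meter of distance to the current target
#'   (positive = commitment: switching less likely close to the site).
#' @param beta_time Slope per second of site occupancy (negative = sunk cost).
#' @param alpha Baseline switch log-odds.
#' @param informed_social_discount Factor in `[0, 1]` multiplying the social
#'   terms (`w_social`, `beta_ds`) for informed agents; at 0, informed agents
#'   never abandon the correct site.
#' @param explore_policy How agents in the local condition pick a site to
#'   inspect before any size is known: `"nearest_unexplored"` or
#'   `"random_unexplored"`.
#' @param policy `"perception"` for the full model; `"random_consensus"` for
#'   the chance-level baseline in which the whole group herds onto one
#'   uniformly drawn site with no perception and no switching.
#' @param prior_radius Radius (m) an agent imputes for a site whose size it
#'   has not yet observed (local condition). An optimistic prior slightly
#'   above the incorrect-site radius makes unexplored sites worth visiting,
#'   producing sequential search.
#'
#' @return An object of class `agent_params` (named list).
#' @export
#' @examples
#' agent_params()
agent_params <- function(sigma_percept = 1,
                         w_social = 0.5,
                         beta_ds = 0.3,
                         beta_dist = 0.02,
                         beta_time = -0.05,
                         alpha = -3,
                         informed_social_discount = 0,
                         explore_policy = c("nearest_unexplored", "random_unexplored"),
                         policy = c("perception", "random_consensus"),
                         prior_radius = 14) {
  explore_policy <- match.arg(explore_policy)
  policy <- match.arg(policy)
  stopifnot(sigma_percept >= 0, w_social >= 0,
            informed_social_discount >= 0, informed_social_discount <= 1)
  structure(
    list(sigma_percept = sigma_percept, w_social = w_social,
         beta_ds = beta_ds, beta_dist = beta_dist, beta_time = beta_time,
         alpha = alpha, informed_social_discount = informed_social_discount,
         explore_policy = explore_policy, policy = policy,
         prior_radius = prior_radius),
    class = "agent_params"
  )
}

SITES <- c("A", "B", "C", "D")

#' A single simulated agent's state
#'
#' Mainly useful for testing the decision rules in isolation;
#' [simulate_trial()] manages states internally.
#'
#' @param x,y Position (m). @param heading Heading (rad).
#' @param informed Whether the agent knows the correct site.
#' @param noise Length-4 perception noise, one draw per site (m).
#' @param perceived Length-4 perceived radii; `NA` = not yet revealed.
#' @param target Current target site label or `NA`.
#' @param goal_x,goal_y Halt point inside the target disc.
#' @param occupancy Seconds spent occupying the current target.
#' @return A list of class `agent_state`.
#' @export
agent_state <- function(x = 0, y = 0, heading = 0, informed = FALSE,
                        noise = rep(0, 4), perceived = rep(NA_real_, 4),
                        target = NA_character_, goal_x = NA_real_,
                        goal_y = NA_real_, occupancy = 0) {
  structure(
    list(x = x, y = y, heading = heading, informed = informed,
         noise = stats::setNames(noise, SITES),
         perceived = stats::setNames(perceived, SITES),
         target = target, goal_x = goal_x, goal_y = goal_y,
         occupancy = occupancy, arrived = FALSE),
    class = "agent_state"
  )
}

#' Reveal perceived site radii
#'
#' In the global and informed-minority conditions every site's perceived
#' radius is the true radius plus the agent's fixed perception noise. In the
#' local condition a site is revealed only once the agent has come within
#' `config$local_visibility_radius` of its center; revelation is permanent.
#' Informed agents additionally know the correct site's label exactly
#' (tracked by the `informed` flag, not by altering radii).
#'
#' @param state An [agent_state()].
#' @param config A [trial_config()].
#' @return The state with its `perceived` vector updated.
#' @export
perceive_sites <- function(state, config) {
  truth <- config$sites$radius
  if (config$condition == "local") {
    d <- sqrt((config$sites$x - state$x)^2 + (config$sites$y - state$y)^2)
    reveal <- d <= config$local_visibility_radius & is.na(state$perceived)
    state$perceived[reveal] <- truth[reveal] + state$noise[reveal]
  } else if (anyNA(state$perceived)) {
    state$perceived <- stats::setNames(truth + state$noise, SITES)
  }
  state
}

# ranking helper: break ties by perceived radius (unknown sites imputed at
# the optimistic prior), then label order
pick_site <- function(score, perceived, prior_radius = 14) {
  perc <- ifelse(is.na(perceived), prior_radius, perceived)
  ord <- order(-score, -perc, SITES)
  SITES[ord[1]]
}

draw_goal <- function(site_row) {
  r <- site_row$radius * sqrt(stats::runif(1))
  a <- stats::runif(1, 0, 2 * pi)
  c(site_row$x + r * cos(a), site_row$y + r * sin(a))
}

#' One decision tick of a simulated agent
#'
#' Runs, in order: perception ([perceive_sites()]); target selection if the
#' agent has none (argmax over known sites of perceived radius +
#' `w_social` x supporter count, exploration fallback when nothing is known);
#' the logistic switch hazard
#' `p = plogis(alpha + beta_ds * ds + beta_dist * d + beta_time * tau)`
#' with the new target on a switch being the most supported alternative
#' (ties broken by larger perceived radius, then label order); and one second
#' of kinematic integration toward the goal point (rotation capped at
#' `rot_rate`, forward motion at `speed` gated on a heading error below 15
#' degrees, halting at the goal).
#'
#' @param state An [agent_state()].
#' @param social_counts Named length-4 integer vector: how many *other*
#'   individuals currently support each site.
#' @param params An [agent_params()].
#' @param config A [trial_config()].
#' @return The updated state; attribute `"trace"` holds the within-tick pose
#'   trace (matrix with columns x, y, heading, one row per kinematic substep).
#' @export
agent_step <- function(state, social_counts, params, config) {
  state <- agent_decide(state, social_counts, params, config)
  state <- integrate_tick(state, config)
  state
}

# decision stage of a tick: perception, reveal-triggered re-evaluation,
# target selection, switch hazard
agent_decide <- function(state, social_counts, params, config) {
  known_before <- !is.na(state$perceived)
  state <- perceive_sites(state, config)
  discount <- if (state$informed) params$informed_social_discount else 1
  revealed_now <- !is.na(state$perceived) & !known_before
  if (any(revealed_now) && !is.na(state$target) &&
      config$condition == "local" && params$policy == "perception" &&
      !state$informed) {
    # new size information: re-evaluate the target choice in full
    perc <- ifelse(is.na(state$perceived), params$prior_radius, state$perceived)
    score <- perc + discount * params$w_social * social_counts
    best <- pick_site(score, state$perceived, params$prior_radius)
    if (best != state$target) {
      state$target <- best
      g <- draw_goal(site_lookup(config, best))
      state$goal_x <- g[1]; state$goal_y <- g[2]
      state$arrived <- FALSE
      state$occupancy <- 0
      return(state)
    }
  }
  if (is.na(state$target)) {
    state <- select_target(state, social_counts, params, config, discount)
  } else if (params$policy != "random_consensus") {
    counts <- social_counts
    cur <- state$target
    ds <- max(counts[SITES != cur]) - counts[[cur]]
    d <- dist_to_site(state, site_lookup(config, cur))
    eta <- params$alpha + discount * params$beta_ds * ds +
      params$beta_dist * d + params$beta_time * state$occupancy
    p <- stats::plogis(eta)
    locked <- state$informed && params$informed_social_discount == 0 &&
      cur == config$correct_site
    if (!locked && stats::runif(1) < p) {
      alt <- SITES[SITES != cur]
      perc <- ifelse(is.na(state$perceived), params$prior_radius, state$perceived)
      score <- stats::setNames(rep(-Inf, 4), SITES)
      score[alt] <- perc[alt] + discount * params$w_social * social_counts[alt]
      new <- pick_site(score, state$perceived, params$prior_radius)
      state$target <- new
      g <- draw_goal(site_lookup(config, new))
      state$goal_x <- g[1]; state$goal_y <- g[2]
      state$arrived <- FALSE
      state$occupancy <- 0
    }
  }
  state
}

select_target <- function(state, social_counts, params, config, discount) {
  known <- !is.na(state$perceived)
  if (params$policy == "random_consensus") {
    # caller assigns the group's site; nothing to do here
    return(state)
  }
  if (state$informed) {
    tgt <- config$correct_site
  } else if (any(known)) {
    score <- stats::setNames(rep(-Inf, 4), SITES)
    score[known] <- state$perceived[known] +
      discount * params$w_social * social_counts[known]
    tgt <- pick_site(score, state$perceived, params$prior_radius)
  } else {
    unexplored <- SITES[is.na(state$perceived)]
    if (params$explore_policy == "nearest_unexplored") {
      d <- vapply(unexplored, function(s) dist_to_site(state, site_lookup(config, s)),
                  numeric(1))
      tgt <- unexplored[which.min(d)]
    } else {
      tgt <- sample(unexplored, 1)
    }
  }
  state$target <- tgt
  g <- draw_goal(site_lookup(config, tgt))
  state$goal_x <- g[1]; state$goal_y <- g[2]
  state$arrived <- FALSE
  state$occupancy <- 0
  state
}

dist_to_site <- function(state, site_row) {
  sqrt((site_row$x - state$x)^2 + (site_row$y - state$y)^2)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# vectorised kinematic substep shared by agent_step and simulate_trial
step_motion <- function(x, y, heading, gx, gy, speed, rot_rate, dt, active,
                        half_extent) {
  desired <- atan2(gy - y, gx - x)
  err <- wrap_angle(desired - heading)
  turn <- pmax(pmin(err, rot_rate * dt), -rot_rate * dt)
  heading <- wrap_angle(heading + turn)
  err2 <- wrap_angle(desired - heading)
  dist_goal <- sqrt((gx - x)^2 + (gy - y)^2)
  can_move <- active & abs(err2) < (15 * pi / 180) & dist_goal > 1e-9
  step <- ifelse(can_move, pmin(speed * dt, dist_goal), 0)
  x <- pmin(pmax(x + cos(heading) * step, -half_extent), half_extent)
  y <- pmin(pmax(y + sin(heading) * step, -half_extent), half_extent)
  list(x = x, y = y, heading = heading)
}

integrate_tick <- function(state, config) {
  n_sub <- config$sample_rate
  dt <- 1 / n_sub
  trace <- matrix(NA_real_, n_sub, 3, dimnames = list(NULL, c("x", "y", "heading")))
  active <- !is.na(state$target)
  gx <- if (active) state$goal_x else state$x
  gy <- if (active) state$goal_y else state$y
  for (k in seq_len(n_sub)) {
    m <- step_motion(state$x, state$y, state$heading, gx, gy,
                     config$speed, config$rot_rate, dt, active,
                     config$arena_half_extent)
    state$x <- m$x; state$y <- m$y; state$heading <- m$heading
    trace[k, ] <- c(state$x, state$y, state$heading)
  }
  if (active && sqrt((gx - state$x)^2 + (gy - state$y)^2) < 1e-6) {
    state$arrived <- TRUE
  }
  inside <- active && state$arrived &&
    dist_to_site(state, site_lookup(config, state$target)) <
      site_lookup(config, state$target)$radius
  state$occupancy <- if (inside) state$occupancy + 1 else 0
  attr(state, "trace") <- trace
  state
}

#' Simulate one trial
#'
#' Runs the full agent-based model for one trial: participants start at
#' uniformly random positions within `start_radius` of the arena center with
#' uniform headings, perceive (and in the local condition progressively
#' reveal) site radii, pick targets, and re-evaluate their choice through the
#' switch hazard once per second. The trial ends at the first second at which
#' every participant is inside the same site disc, or at the time limit.
#' Deterministic given `seed`.
#'
#' @param config A [trial_config()].
#' @param params An [agent_params()].
#' @param seed Integer seed for the trial's RNG stream.
#' @param trial_id Label for the trial.
#' @param return_trajectories Set to `FALSE` to skip building the trajectory
#'   tibble (outcome only; much faster for large batches).
#' @return A list of class `arena_trial` with elements `trajectories`
#'   (tibble in the standard dialect, or `NULL`), `outcome` (one-row tibble:
#'   `trial_id, condition, difficulty, n_participants, seed, consensus_site,
#'   consensus_time, outcome, success, gold`), `config`, `params`, `seed`.
#' @export
#' @examples
#' cfg <- trial_config("global", "easy", n_participants = 7)
#' tr <- simulate_trial(cfg, agent_params(sigma_percept = 0, w_social = 0), seed = 1)
#' tr$outcome
simulate_trial <- function(config, params = agent_params(), seed,
                           trial_id = "trial1", return_trajectories = TRUE) {
  stopifnot(inherits(config, "trial_config"), inherits(params, "agent_params"))
  withr::with_seed(as.integer(seed), {
    n <- config$n_participants
    n_sub <- config$sample_rate
    dt <- 1 / n_sub
    # starting poses: uniform in the start disc, uniform headings
    r0 <- config$start_radius * sqrt(stats::runif(n))
    a0 <- stats::runif(n, 0, 2 * pi)
    x <- r0 * cos(a0); y <- r0 * sin(a0)
    heading <- stats::runif(n, -pi, pi)
    informed <- config$participants %in% config$informed_ids
    noise <- matrix(stats::rnorm(n * 4, 0, params$sigma_percept), n, 4,
                    dimnames = list(NULL, SITES))
    states <- lapply(seq_len(n), function(i) {
      agent_state(x = x[i], y = y[i], heading = heading[i],
                  informed = informed[i], noise = noise[i, ])
    })
    if (params$policy == "random_consensus") {
      grp_site <- sample(SITES, 1)
      for (i in seq_len(n)) {
        states[[i]]$target <- grp_site
        g <- draw_goal(site_lookup(config, grp_site))
        states[[i]]$goal_x <- g[1]; states[[i]]$goal_y <- g[2]
      }
    }
    n_steps_max <- config$time_limit * n_sub + 1
    X <- matrix(NA_real_, n_steps_max, n)
    Y <- matrix(NA_real_, n_steps_max, n)
    H <- matrix(NA_real_, n_steps_max, n)
    X[1, ] <- x; Y[1, ] <- y; H[1, ] <- heading
    consensus_site <- NA_character_
    consensus_time <- NA_real_
    row <- 1L
    site_idx <- stats::setNames(seq_along(SITES), SITES)
    for (s in seq_len(config$time_limit) - 1L) {
      if (params$policy != "random_consensus") {
        targets <- vapply(states, function(st) st$target, character(1))
        counts_all <- tabulate(site_idx[targets[!is.na(targets)]], 4L)
        for (i in seq_len(n)) {
          own <- stats::setNames(counts_all, SITES)
          if (!is.na(targets[i])) own[targets[i]] <- own[targets[i]] - 1L
          states[[i]] <- agent_decide(states[[i]], own, params, config)
        }
      }
      # vectorised kinematics over all agents for this second
      px <- vapply(states, function(st) st$x, numeric(1))
      py <- vapply(states, function(st) st$y, numeric(1))
      ph <- vapply(states, function(st) st$heading, numeric(1))
      active <- !vapply(states, function(st) is.na(st$target), logical(1))
      gx <- ifelse(active, vapply(states, function(st) st$goal_x, numeric(1)), px)
      gy <- ifelse(active, vapply(states, function(st) st$goal_y, numeric(1)), py)
      for (k in seq_len(n_sub)) {
        m <- step_motion(px, py, ph, gx, gy, config$speed, config$rot_rate,
                         dt, active, config$arena_half_extent)
        px <- m$x; py <- m$y; ph <- m$heading
        r <- row + k
        X[r, ] <- px; Y[r, ] <- py; H[r, ] <- ph
      }
      at_goal <- sqrt((gx - px)^2 + (gy - py)^2) < 1e-6
      occ_now <- occupied_site(px, py, config)
      for (i in seq_len(n)) {
        st <- states[[i]]
        st$x <- px[i]; st$y <- py[i]; st$heading <- ph[i]
        if (active[i] && at_goal[i]) st$arrived <- TRUE
        inside <- active[i] && st$arrived && !is.na(occ_now[i]) &&
          occ_now[i] == st$target
        st$occupancy <- if (inside) st$occupancy + 1 else 0
        states[[i]] <- st
      }
      row <- row + n_sub
      if (!anyNA(occ_now) && length(unique(occ_now)) == 1) {
        consensus_site <- occ_now[1]
        consensus_time <- s + 1
        break
      }
    }
    traj <- NULL
    if (return_trajectories) {
      keep <- seq_len(row)
      tvals <- (keep - 1) * dt
      traj <- tibble::tibble(
        trial_id = trial_id,
        participant_id = rep(config$participants, each = length(keep)),
        t = rep(tvals, n),
        x = as.vector(X[keep, ]),
        y = as.vector(Y[keep, ]),
        heading = as.vector(H[keep, ]),
        informed = rep(informed, each = length(keep))
      )
    }
    outcome <- score_trial(consensus_site, consensus_time, config,
                           trial_id = trial_id)
    outcome$seed <- as.integer(seed)
    structure(
      list(trajectories = traj, outcome = outcome, config = config,
           params = params, seed = as.integer(seed)),
      class = "arena_trial"
    )
  })
}

# which site disc (strictly inside) each position falls in; NA if none
occupied_site <- function(x, y, config) {
  out <- rep(NA_character_, length(x))
  sx <- config$sites$x; sy <- config$sites$y
  sr <- config$sites$radius; sid <- config$sites$id
  for (k in seq_along(sid)) {
    inside <- (x - sx[k])^2 + (y - sy[k])^2 < sr[k]^2
    out[inside] <- sid[k]
  }
  out
}

#' Simulate a batch of trials over a design grid
#'
#' Crosses the requested conditions and difficulties, simulates `n_per_cell`
#' trials per cell with per-trial seeds derived reproducibly from
#' `master_seed`, and returns the pooled outcomes (the batch manifest) plus,
#' optionally, the pooled trajectory table.
#'
#' @param conditions,difficulties Character vectors defining the design grid.
#' @param n_per_cell Trials per condition-by-difficulty cell.
#' @param params An [agent_params()].
#' @param master_seed Integer master seed.
#' @param keep_trajectories Keep the (large) pooled trajectory tibble?
#' @param ... Further arguments passed to [trial_config()] (e.g.
#'   `n_participants`, `sample_rate`).
#' @return A list of class `arena_batch`: `outcomes` (tibble, one row per
#'   trial incl. per-trial seed), `trajectories` (tibble or `NULL`),
#'   `configs` (named list of the cell configs), `master_seed`.
#' @export
simulate_batch <- function(conditions = c("global", "local", "informed_minority"),
                           difficulties = c("easy", "medium", "hard"),
                           n_per_cell = 1,
                           params = agent_params(),
                           master_seed = 1,
                           keep_trajectories = TRUE,
                           ...) {
  stopifnot(n_per_cell >= 1)
  grid <- expand.grid(condition = conditions, difficulty = difficulties,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  seeds <- withr::with_seed(as.integer(master_seed),
                            sample.int(.Machine$integer.max - 1L, nrow(grid)))
  configs <- list()
  for (cond in conditions) {
    for (diff in difficulties) {
      configs[[paste(cond, diff, sep = "_")]] <-
        trial_config(condition = cond, difficulty = diff, ...)
    }
  }
  trials <- purrr::pmap(
    list(grid$condition, grid$difficulty, grid$rep, seeds),
    function(cond, diff, rep, seed) {
      cfg <- configs[[paste(cond, diff, sep = "_")]]
      simulate_trial(cfg, params, seed = seed,
                     trial_id = sprintf("%s_%s_%04d", cond, diff, rep),
                     return_trajectories = keep_trajectories)
    }
  )
  outcomes <- purrr::list_rbind(purrr::map(trials, "outcome"))
  traj <- if (keep_trajectories) {
    purrr::list_rbind(purrr::map(trials, "trajectories"))
  }
  structure(
    list(outcomes = outcomes, trajectories = traj, configs = configs,
         master_seed = as.integer(master_seed)),
    class = "arena_batch"
  )
}
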