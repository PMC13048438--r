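#' Plot trial trajectories over the arena
#'
#' Draws participant paths with the four candidate sites; the correct site
#' is outlined in a distinct colour.
#'
#' @param traj A trajectory tibble (one trial).
#' @param config A [trial_config()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, config) {
  circ <- purrr::map(seq_len(nrow(config$sites)), function(k) {
    a <- seq(0, 2 * pi, length.out = 120)
    tibble::tibble(
      id = config$sites$id[k],
      x = config$sites$x[k] + config$sites$radius[k] * cos(a),
      y = config$sites$y[k] + config$sites$radius[k] * sin(a),
      correct = config$sites$id[k] == config$correct_site
    )
  }) |> purrr::list_rbind()
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   colour = .data$correct),
      linewidth = 0.8, show.legend = FALSE
    ) +
    ggplot2::geom_path(
      data = traj,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$participant_id),
      alpha = 0.6
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "grey40")) +
    ggplot2::coord_equal(
      xlim = c(-config$arena_half_extent, config$arena_half_extent),
      ylim = c(-config$arena_half_extent, config$arena_half_extent)
    ) +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = paste(config$condition, config$difficulty, sep = " / ")) +
    ggplot2::theme_minimal()
}

#' Success probabilities by condition and difficulty
#'
#' @param object An `arena_summary` from [summarize_outcomes()].
#' @param ... Unused.
#' @return A ggplot object (points with 95% Wilson intervals, faceted by
#'   condition).
#' @method autoplot arena_summary
#' @export
autoplot.arena_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$difficulty, y = .data$success_prop)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$success_lo,
                                          ymax = .data$success_hi)) +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "difficulty", y = "P(correct consensus)",
                  caption = "dashed line: 25% chance level") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Predicted switch-probability curves
#'
#' @param fit A binomial `arena_fit` (see [predicted_switch_curve()]).
#' @param grid DeltaSocial grid.
#' @param by Optional factor name: one curve per level.
#' @return A ggplot object.
#' @export
plot_switch_curve <- function(fit, grid = seq(-9, 9, by = 0.5), by = NULL) {
  curves <- if (is.null(by)) {
    predicted_switch_curve(fit, grid) |> dplyr::mutate(level = "all")
  } else {
    purrr::map(sort(unique(as.character(fit$data[[by]]))), function(lv) {
      at <- stats::setNames(list(lv), by)
      predicted_switch_curve(fit, grid, at = at) |>
        dplyr::mutate(level = lv)
    }) |> purrr::list_rbind()
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$delta_social, y = .data$prob,
                                       colour = .data$level)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::labs(x = "DeltaSocial", y = "P(switch)",
                  colour = by %||% NULL) +
    ggplot2::theme_minimal()
}
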