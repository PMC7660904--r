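#' Plot a marginal distribution
#'
#' Mass over the within-host frequency grid; a log y-scale (default) makes
#' boundary spikes and bimodality visible across orders of magnitude.
#'
#' @param object A `marginal_distribution`.
#' @param log_y Use a log10 y-axis, dropping zero-mass states.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marginal_distribution
#' @export
autoplot.marginal_distribution <- function(object, log_y = TRUE, ...) {
  df <- tidy(object)
  target <- attr(object, "target")
  xlab <- if (!is.null(target) && target$kind == "empty_space")
    "within-host frequency of empty space, x0"
  else "within-host frequency, x"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$mass)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = xlab, y = "stationary mass") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a population trajectory
#'
#' Focal-type frequency against time, one line per host.
#'
#' @param object A `population_trajectory`.
#' @param target Focal target to display (default taxon 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_trajectory
#' @export
autoplot.population_trajectory <- function(object, target = focal_taxon(1), ...) {
  assert_target(target, object$params)
  want <- if (target$kind == "taxon") target$taxon_index else 0L
  df <- dplyr::filter(as_tibble(object), .data$type_index == want)
  df$frequency <- df$count / object$params$N
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency,
                                   group = .data$host_id)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.2) +
    ggplot2::labs(x = "time (microbial death-birth events)",
                  y = "focal frequency") +
    ggplot2::theme_minimal()
}

#' Phase-map plot of a sweep result
#'
#' Tile map over the (m, tau) grid, filled by a chosen summary column.
#'
#' @param x A [run_sweep()] result.
#' @param fill Column to map to fill: `"modality"`, `"p_absent"`,
#'   `"p_present"`, `"p_full"` or `"tv_to_tau0"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(x, fill = c("modality", "p_absent", "p_present",
                                   "p_full", "tv_to_tau0")) {
  stopifnot(inherits(x, "sweep_result"))
  fill <- match.arg(fill)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$m, y = .data$tau,
                                  fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "migration probability m",
                  y = "host death-birth probability tau") +
    ggplot2::theme_minimal()
}

#' @rdname plot_sweep
#' @param object A [run_sweep()] result.
#' @param ... Passed to [plot_sweep()].
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) plot_sweep(object, ...)
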