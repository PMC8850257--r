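#' Plot mean response curves for one or several nominal parameter sets
#'
#' @param prior A [parameter_prior()] (or a single parameter vector).
#' @param interval Dose interval to draw over.
#' @param n_grid Number of curve points.
#' @return A ggplot.
#' @export
plot_response_curves <- function(prior, interval, n_grid = 301) {
  if (!inherits(prior, "parameter_prior")) prior <- parameter_prior(list(as_theta(prior)))
  xs <- seq(interval[1], interval[2], length.out = n_grid)
  df <- purrr::map2_dfr(prior_thetas(prior), prior$set, function(th, lbl) {
    tibble(set = lbl, dose = xs, response = mean_response(th, xs))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$response,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "dose (uM)", y = "mean response rate") +
    ggplot2::theme_minimal()
}

#' @rdname plot_response_curves
#' @param object A [parameter_prior()].
#' @param ... Passed to `plot_response_curves()` (must include `interval`).
#' @method autoplot parameter_prior
#' @export
autoplot.parameter_prior <- function(object, ...) {
  plot_response_curves(object, ...)
}

#' Plot a design as weighted support spikes
#'
#' @param object A [design()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_design
#' @export
autoplot.dose_design <- function(object, ...) {
  iv <- design_interval(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose, y = .data$weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$dose, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::xlim(iv[1], iv[2]) +
    ggplot2::labs(x = "dose (uM)", y = "design weight") +
    ggplot2::theme_minimal()
}
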