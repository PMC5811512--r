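#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a state trajectory
#'
#' One line per state of the scheme: closed states, open state, blocked
#' state, over time.
#'
#' @param object A [trajectory()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot channel_trajectory
#' @export
autoplot.channel_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$probability,
                               colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "state probability",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a region map of peak behaviour
#'
#' Tile plot of the classified parameter plane: either the
#' dissociation-rate/voltage plane (labels A1/A2/A3) or the
#' closing-rate/dissociation-rate plane (peak / no_peak). The dissociation
#' axis is drawn on a log scale.
#'
#' @param object A `region_map` from [scan_delta_v_plane()] or
#'   [scan_beta_delta_plane()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_map
#' @export
autoplot.region_map <- function(object, ...) {
  axes <- attr(object, "axes")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data[[axes[2]]],
                                    y = .data[[axes[1]]],
                                    fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
  if (identical(axes, c("delta", "v"))) {
    p + ggplot2::labs(x = "membrane potential (mV)",
                      y = "dissociation rate (1/ms)", fill = "region")
  } else {
    p + ggplot2::labs(x = "dissociation rate (1/ms)",
                      y = "closing rate (1/ms)", fill = "peak")
  }
}

#' Plot a Monte Carlo ensemble estimate
#'
#' Open-probability estimate with a pointwise 3-standard-error ribbon.
#'
#' @param object An [ensemble_open_probability()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_estimate
#' @export
autoplot.ensemble_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$open_prob)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$open_prob - 3 * .data$stderr),
                   ymax = pmin(1, .data$open_prob + 3 * .data$stderr)),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "open probability") +
    ggplot2::theme_minimal()
}
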