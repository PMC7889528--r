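#' Plot a trace against time and temperature
#'
#' Value versus time with the temperature ramp overlaid on a secondary
#' axis - the standard way turbidity traces are displayed in this assay.
#'
#' @param object A `cp_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cp_trace <- function(object, ...) {
  rng_v <- range(object$value, finite = TRUE)
  rng_t <- range(object$temp_C, finite = TRUE)
  if (diff(rng_v) == 0) rng_v <- rng_v + c(-0.5, 0.5)
  scale <- diff(rng_v) / diff(rng_t)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(
      y = (.data$temp_C - rng_t[1]) * scale + rng_v[1]),
      color = "grey60", linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), color = "#1b6ca8") +
    ggplot2::scale_y_continuous(
      name = object$strategy[1],
      sec.axis = ggplot2::sec_axis(~ (. - rng_v[1]) / scale + rng_t[1],
                                   name = "temperature (°C)")) +
    ggplot2::labs(x = "time (s)",
                  title = sprintf("%s - well %s", object$strategy[1],
                                  object$well_id[1])) +
    ggplot2::theme_minimal()
}

#' Plot several traces faceted by strategy
#'
#' @param traces Long trace tibble from [extract_traces()].
#' @param x `"time_s"` or `"temp_C"`.
#' @return A ggplot.
#' @export
plot_traces <- function(traces, x = c("time_s", "temp_C")) {
  x <- match.arg(x)
  p <- ggplot2::ggplot(traces, ggplot2::aes(
    x = .data[[x]], y = .data$value, color = .data$well_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~strategy, scales = "free_y") +
    ggplot2::labs(x = if (x == "time_s") "time (s)" else "temperature (°C)",
                  y = NULL, color = "well") +
    ggplot2::theme_minimal()
  if (x == "temp_C") p <- p + ggplot2::scale_x_reverse()
  p
}

#' Scatter of paired strategy detections
#'
#' Cloud points of one strategy against the other with the identity line -
#' points on the line mean the strategies agree.
#'
#' @param object A [compare_strategies()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  s <- object$strategies
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data[[s[1]]], y = .data[[s[2]]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(color = "#1b6ca8", alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("%s %s (°C)", s[1], object$value),
      y = sprintf("%s %s (°C)", s[2], object$value),
      subtitle = sprintf("total RMSE %.2f °C, average %.2f °C, R² %.3f",
                         object$total_rmse, object$average_rmse,
                         object$r_squared)) +
    ggplot2::theme_minimal()
}
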