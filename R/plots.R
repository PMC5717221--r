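#' Plot methods for curves and curve series
#'
#' `autoplot()` draws a theory curve (`lgca_curve`) as a line, and an
#' estimator series (`curve_series`) as points with a 3-SEM ribbon.
#' [plot_curve_comparison()] overlays an empirical series on its matching
#' theory curve, the standard theory-vs-simulation diagnostic.
#'
#' @param object An `lgca_curve` or `curve_series`.
#' @param log_log Draw on log-log axes (default `TRUE` for MSD curves).
#' @param ... Unused.
#' @return A ggplot object.
#' @name lgca-plots
NULL

#' @rdname lgca-plots
#' @importFrom ggplot2 autoplot
#' @method autoplot lgca_curve
#' @export
autoplot.lgca_curve <- function(object, log_log = NULL, ...) {
  meta <- attr(object, "meta")
  lab <- if (identical(meta$kind, "msd")) "MSD" else "VACF"
  if (is.null(log_log)) log_log <- identical(meta$kind, "msd")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "t", y = lab) +
    ggplot2::theme_minimal()
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @rdname lgca-plots
#' @method autoplot curve_series
#' @export
autoplot.curve_series <- function(object, log_log = NULL, ...) {
  meta <- attr(object, "meta")
  lab <- if (identical(meta$kind, "msd")) "MSD" else "VACF"
  if (is.null(log_log)) log_log <- identical(meta$kind, "msd")
  df <- object[object$k > 0 | !log_log, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - 3 * .data$sem,
                                      ymax = .data$value + 3 * .data$sem),
                         fill = "grey80") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "t", y = lab) +
    ggplot2::theme_minimal()
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @rdname lgca-plots
#' @param empirical A `curve_series` (simulation estimate).
#' @param theory An `lgca_curve` (matching closed form).
#' @export
plot_curve_comparison <- function(empirical, theory, log_log = NULL) {
  meta <- attr(empirical, "meta")
  lab <- if (identical(meta$kind, "msd")) "MSD" else "VACF"
  if (is.null(log_log)) log_log <- identical(meta$kind, "msd")
  emp <- empirical[empirical$k > 0 | !log_log, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = emp,
      ggplot2::aes(x = .data$t, ymin = .data$value - 3 * .data$sem,
                   ymax = .data$value + 3 * .data$sem),
      fill = "grey80") +
    ggplot2::geom_point(data = emp,
                        ggplot2::aes(x = .data$t, y = .data$value),
                        size = 0.8) +
    ggplot2::geom_line(data = theory,
                       ggplot2::aes(x = .data$t, y = .data$value),
                       color = "firebrick") +
    ggplot2::labs(x = "t", y = lab,
                  subtitle = "points: simulation (±3 SEM), line: theory") +
    ggplot2::theme_minimal()
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}
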