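#' Plot methods
#'
#' `autoplot()` methods for the package's result types: the individual-TCP
#' histogram of a [population_tcp()] result (the dichotomy of the
#' two-fraction schedule is visible as a spike near zero), the dose-response
#' curve of a [dose_sweep()], and the paired-TCP scatter of a
#' [sensitivity_grid()].
#'
#' @param object A result object.
#' @param n_bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @name zmtcp-plots
NULL

#' @rdname zmtcp-plots
#' @method autoplot population_tcp
#' @export
autoplot.population_tcp <- function(object, n_bins = 50, ...) {
  h <- tcp_histogram(object, n_bins = n_bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 1 / n_bins, fill = "steelblue") +
    ggplot2::labs(
      x = "individual TCP", y = "patients",
      title = sprintf("Population TCP %.1f%% (n = %d)",
                      100 * object$population_tcp, nrow(object$individuals))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname zmtcp-plots
#' @method autoplot tcp_dose_sweep
#' @export
autoplot.tcp_dose_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy,
                                       y = 100 * .data$population_tcp)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "dose per fraction (Gy)", y = "population TCP (%)") +
    ggplot2::theme_minimal()
}

#' @rdname zmtcp-plots
#' @method autoplot tcp_sensitivity_grid
#' @export
autoplot.tcp_sensitivity_grid <- function(object, ...) {
  base <- dplyr::filter(object, .data$parameter == "base")
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$tcp_3f,
                                       y = 100 * .data$tcp_2f,
                                       color = .data$parameter)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = base, color = "red", size = 3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "population TCP, 3-fraction schedule (%)",
                  y = "population TCP, 2-fraction schedule (%)") +
    ggplot2::theme_minimal()
}
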