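#' Plot an annual standardized incidence series
#'
#' Line of the directly standardized rate per 100,000 with its Gamma-method
#' interval as a ribbon.
#'
#' @param object A `cd_rate_series` from [incidence_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cd_rate_series
#' @export
autoplot.cd_rate_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$dsr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year",
                  y = "Standardized incidence per 100,000",
                  title = "Age-sex standardized incidence") +
    ggplot2::theme_minimal()
}

#' Forest plot of operating characteristics
#'
#' @param object A `cd_accuracy` tibble.
#' @param ... Unused.
#' @return A ggplot faceted by measure.
#' @method autoplot cd_accuracy
#' @export
autoplot.cd_accuracy <- function(object, ...) {
  if (!"algorithm_id" %in% names(object)) object$algorithm_id <- "(unnamed)"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate,
                               y = .data$algorithm_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%g%%", x * 100)) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL,
                  title = "Algorithm operating characteristics") +
    ggplot2::theme_minimal()
}
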