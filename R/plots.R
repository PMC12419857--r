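#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-response curve
#'
#' Hazard ratio (log scale) with its pointwise confidence band against the
#' exposure, with the reference value and HR = 1 marked.
#'
#' @param object A `dose_response` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$reference, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$exposure, y = "Hazard ratio") +
    ggplot2::theme_minimal()
}

#' Plot a life-expectancy table
#'
#' Residual life expectancy by conditioning age, one line per
#' multimorbidity group, with confidence ribbons when present.
#'
#' @param object An [le_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.le_table <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$le,
                                            colour = .data$group,
                                            fill = .data$group))
  if (!all(is.na(object$le_low))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$le_low,
                                               ymax = .data$le_high),
                                  alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Conditioning age (years)",
                  y = "Residual life expectancy (years)") +
    ggplot2::theme_minimal()
}

#' Forest plot of multistate transition hazard ratios
#'
#' Per-transition hazard ratios with CIs for a chosen covariate (by default
#' the acceleration exposure).
#'
#' @param object A `multistate_fit`.
#' @param term Covariate to display (default `"accel_sd"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.multistate_fit <- function(object, term = "accel_sd", ...) {
  td <- tidy(object)
  td <- td[td$term == term, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$hr, y = .data$transition)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste("Hazard ratio per unit", term),
                  y = NULL) +
    ggplot2::theme_minimal()
}
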