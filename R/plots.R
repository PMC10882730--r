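#' Plot methods
#'
#' `autoplot()` methods turn the package's summary objects into the three
#' standard displays: the register-error boxplot by year
#' ([cdw_error_summary()]), the intervention interaction plot
#' ([interaction_predictions()]), and a forest plot of rate ratios
#' ([rr_summary()]).
#'
#' @param object A summary object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' @rdname autoplot-methods
#' @export
autoplot.cdw_error_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$year), y = .data$pct_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Study year",
                  y = "(register - official) / official x 100",
                  title = "Register error against official estimates") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.interaction_predictions <- function(object, ...) {
  object$coverage_lab <- paste0(object$coverage, "% coverage")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data$rate,
                               colour = .data$coverage_lab,
                               fill = .data$coverage_lab)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Study year",
                  y = "Predicted referrals per 100 CRD patients",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.rr_summary <- function(object, ...) {
  object$parameter <- factor(object$parameter,
                             levels = rev(object$parameter))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rr, y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "Rate ratio (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}
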