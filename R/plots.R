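#' Energy profile of a transition trajectory
#'
#' Well energy of each frame against the energy-domain time, coloured by
#' well; the cusp at the top is the transition state.
#'
#' @param object A `path_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot path_trajectory
#' @export
autoplot.path_trajectory <- function(object, ...) {
  df <- tidy.path_trajectory(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$energy,
                                   colour = .data$well)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (reduced)", y = "well energy",
                  colour = "well") +
    ggplot2::theme_minimal()
}

#' Observed versus predicted values of a regression fit
#' @param object A `path_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot path_fit
#' @export
autoplot.path_fit <- function(object, ...) {
  df <- tibble::tibble(observed = object$response, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "predicted", y = "observed",
      subtitle = sprintf("R² = %.2f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Coefficient histogram of a factorial-design fit
#'
#' Bar chart of the non-intercept regression coefficients (main effects and
#' interactions over the mutated sites), the standard display for which
#' site combinations drive a fitted response.
#'
#' @param fit A `path_fit` from a factorial design.
#' @return A ggplot object.
#' @export
plot_design_effects <- function(fit) {
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  co$term <- factor(co$term, levels = co$term)
  ggplot2::ggplot(co, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$estimate - .data$std_error,
      ymax = .data$estimate + .data$std_error), width = 0.3) +
    ggplot2::labs(x = NULL, y = "coefficient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
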