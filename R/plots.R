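#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_ribbon geom_line
#'   geom_point geom_errorbar geom_abline labs facet_wrap coord_cartesian
#'   scale_y_continuous theme_minimal
NULL

#' Plot a Kaplan-Meier curve
#'
#' Step plot of cumulative event risk `1 - S(t)` with its confidence band.
#'
#' @param object A [km_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1, lower = 1, upper = 1), df)
  ggplot(df, aes(x = .data$time, y = 1 - .data$surv)) +
    geom_ribbon(aes(ymin = 1 - .data$upper, ymax = 1 - .data$lower),
                alpha = 0.2, na.rm = TRUE) +
    geom_step() +
    labs(x = "Years since index assessment", y = "Cumulative event risk") +
    theme_minimal()
}

#' Plot age-standardized cumulative-incidence curves
#'
#' One adjusted incidence curve per exposure group with 95% bands; the
#' display window defaults to the first 8 years of follow-up (estimation
#' always uses all follow-up).
#'
#' @param object An [age_adjusted_curves()] result.
#' @param max_time Right edge of the displayed time axis (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_std_curves <- function(object, max_time = 8, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$time, y = .data$incidence, colour = .data$group,
                 fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.15,
                colour = NA) +
    geom_line() +
    coord_cartesian(xlim = c(0, max_time)) +
    labs(x = "Years since index assessment",
         y = "Age-adjusted cumulative incidence",
         colour = "Group", fill = "Group") +
    theme_minimal()
}

#' Calibration plot (predicted vs observed risk by decile)
#'
#' Mean predicted risk per decile against Kaplan-Meier observed risk with
#' 95% error bars; the diagonal marks perfect calibration, points above it
#' mark underestimation by the equation.
#'
#' @param object A [calibration_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$mean_predicted, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0) +
    geom_point() +
    labs(x = "Mean predicted risk (decile)", y = "Observed risk (Kaplan-Meier)",
         title = attr(object, "population"),
         subtitle = sprintf("mean observed:predicted ratio = %.2f",
                            mean_ratio(object))) +
    theme_minimal()
}

#' @rdname autoplot.calibration_table
#' @export
plot_calibration <- function(object, ...) autoplot.calibration_table(object, ...)

#' @rdname autoplot.age_std_curves
#' @export
plot_incidence <- function(object, ...) autoplot.age_std_curves(object, ...)
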