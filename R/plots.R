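# ggplot2 presentations of the result objects.

#' @describeIn usual_bp_analysis Stratum median-WMH ratios against usual
#'   BP on a log scale, one line per baseline age group.
#' @export
autoplot.usual_bp_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$strata,
    ggplot2::aes(x = .data$usual_bp, y = .data$ratio_to_reference,
                 colour = .data$age_group)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = sprintf("Usual %s (mmHg)", toupper(object$which)),
      y = "Median WMH load, ratio to reference stratum",
      colour = "Baseline age",
      title = sprintf("Median WMH vs usual %s, by baseline age group",
                      toupper(object$which))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_to_reference Median and interquartile range of
#'   logit WMH load per treatment category, faceted by age group.
#' @param object A `treatment_contrasts`.
#' @export
autoplot.treatment_contrasts <- function(object, ...) {
  ggplot2::ggplot(
    object$medians,
    ggplot2::aes(x = .data$category, y = .data$median,
                 ymin = .data$q25, ymax = .data$q75)
  ) +
    ggplot2::geom_pointrange(size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$age_group)) +
    ggplot2::labs(x = NULL, y = "logit WMH load (median, IQR)",
                  title = "WMH load by BP category and treatment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn fit_stratified Forest plot of exposure estimates per
#'   stratum.
#' @param object A `wmh_fit_stratified`.
#' @export
autoplot.wmh_fit_stratified <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(
    td,
    ggplot2::aes(x = .data$estimate, y = .data$stratum,
                 xmin = .data$conf.low, xmax = .data$conf.high,
                 colour = .data$term)
  ) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = sprintf("Coefficient (%s)", td$scale[1]), y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_wmh_model Forest plot of the fitted terms.
#' @export
autoplot.wmh_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(
    td,
    ggplot2::aes(x = .data$estimate, y = stats::reorder(.data$term, .data$estimate),
                 xmin = .data$conf.low, xmax = .data$conf.high)
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = sprintf("Coefficient (%s)", td$scale[1]), y = NULL) +
    ggplot2::theme_minimal()
}
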