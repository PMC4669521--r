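# ggplot2 displays for the package's result types.

#' Plot an association scan as a volcano-style panel
#'
#' Pearson correlation with age against -log10 p per site, with the loose
#' selection thresholds drawn; selected sites are coloured by direction.
#'
#' @param records Association record tibble from [scan_associations()].
#' @param p_max,r2_min Thresholds to draw (defaults 0.01, 0.5).
#' @return A ggplot object.
#' @export
plot_association_scan <- function(records, p_max = 0.01, r2_min = 0.5) {
  check_columns(records, c("R", "p"), "records")
  records$status <- ifelse(records$p < p_max & records$R^2 > r2_min,
    ifelse(records$R > 0, "positive", "negative"), "not selected")
  logp <- -log10(pmax(records$p, 1e-300))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$R, y = logp,
      colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-sqrt(r2_min), sqrt(r2_min)),
      linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "positive" = "#D55E00", "negative" = "#0072B2", "not selected" = "grey70")) +
    ggplot2::labs(x = "Pearson R (beta vs age)", y = "-log10 p",
      colour = NULL, title = "Age-association scan") +
    ggplot2::theme_minimal()
}

#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$measured, y = .data$known)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
      colour = "#0072B2") +
    ggplot2::labs(
      x = "measured methylation", y = "known methylation",
      title = sprintf("Calibration: corrected = %.3f x %+.3f (R² = %.3f)",
        object$slope, object$intercept, object$r2_fit)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot prediction_report
#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(colour = "#0072B2") +
    ggplot2::labs(
      x = "chronological age (years)", y = "predicted age (years)",
      title = sprintf("Predicted vs observed age (MAD %.2f years)",
        attr(object, "mad"))
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot subset_search
#' @export
autoplot.subset_search <- function(object, ...) {
  ggplot2::ggplot(object$by_size, ggplot2::aes(x = .data$size, y = .data$mad)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(colour = "#0072B2") +
    ggplot2::scale_x_continuous(breaks = object$by_size$size) +
    ggplot2::labs(
      x = "number of CpG sites", y = "minimal LOO MAD (years)",
      title = "Exhaustive subset search"
    ) +
    ggplot2::theme_minimal()
}
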