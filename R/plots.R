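# ggplot2 figures for the standard analyses.

#' Plot mean residual error against perturbation size
#'
#' Group mean residual error (baseline-subtracted, left/right pooled) by
#' mean perturbation level and uncertainty class, with the fitted
#' regression lines — the standard summary of uncertainty-dependent
#' partial correction.
#'
#' @param records A response tibble of test-phase trials.
#' @return A ggplot object.
#' @export
plot_residual_errors <- function(records) {
  dat <- baseline_subtract(records) |>
    dplyr::group_by(.data$subject_id, .data$uncertainty, .data$level_p) |>
    dplyr::summarise(bias = mean(.data$delta_adj), .groups = "drop") |>
    dplyr::group_by(.data$uncertainty, .data$level_p) |>
    dplyr::summarise(mean_bias = mean(.data$bias),
                     se = sd(.data$bias) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level_p, y = .data$mean_bias,
                                    color = .data$uncertainty)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_bias - .data$se,
                                          ymax = .data$mean_bias + .data$se)) +
    ggplot2::labs(x = "Mean perturbation (cm)",
                  y = "Mean residual error (cm)",
                  color = "Uncertainty") +
    ggplot2::theme_minimal()
}

#' Plot a binned bias curve
#'
#' Mean residual error as a function of center-of-mass location, one
#' line per perturbation level: vertical separation between the levels
#' in the high-uncertainty regions is the signature of partial
#' correction.
#'
#' @param curve A tibble from [bias_curve()].
#' @return A ggplot object.
#' @export
plot_bias_curve <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data$bin_mid, y = .data$mean_bias,
                               color = factor(.data$perturbation_level))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_bias - .data$se_bias,
      ymax = .data$mean_bias + .data$se_bias)) +
    ggplot2::labs(x = "Center of mass location (cm)",
                  y = "Mean residual error (cm)",
                  color = "Perturbation (cm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.comreach_bias_curve <- function(object, ...) {
  plot_bias_curve(object)
}

#' Plot data-versus-model slope agreement
#'
#' Per-subject uncorrected-fraction slopes measured from data against
#' the slopes predicted by the fitted observer model, with the identity
#' line.
#'
#' @param agreement A [slope_agreement()] object.
#' @return A ggplot object.
#' @export
plot_slope_agreement <- function(agreement) {
  ggplot2::ggplot(agreement$pairs,
                  ggplot2::aes(x = .data$model_slope, y = .data$data_slope,
                               color = .data$uncertainty_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Model-predicted slope", y = "Measured slope",
      color = "Uncertainty",
      subtitle = sprintf("R² = %.2f", agreement$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.slope_agreement <- function(object, ...) {
  plot_slope_agreement(object)
}
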