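#' Plot a fitted calibration curve over its data
#'
#' Observed per-dose MN yields with the fitted linear-quadratic curve and,
#' when a coefficient covariance is available, the 95% delta-method band.
#'
#' @param object An [fit_lq()] object.
#' @param n_grid Number of dose grid points for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lq_fit <- function(object, n_grid = 200, ...) {
  data <- add_mn_totals(object$data)
  data$yield <- data$n_mn / data$n_bn
  grid <- tibble::tibble(dose_gy = seq(0, max(data$dose_gy), length.out = n_grid))
  grid$yield <- predict_yield(object, grid$dose_gy)
  grid$se <- yield_se(object, grid$dose_gy)
  z <- qnorm(0.975)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$dose_gy, y = .data$yield)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$yield - z * .data$se,
                                      ymax = .data$yield + z * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = data) +
    ggplot2::labs(x = "Dose (Gy)", y = "MN per BN cell",
                  title = "Linear-quadratic MN dose-response curve") +
    ggplot2::theme_minimal()
}

#' Plot dose estimates against delivered doses
#'
#' Estimated dose with 95% confidence bars versus the known delivered dose,
#' with the identity line and a +/- 0.5 Gy tolerance band.
#'
#' @param estimates A data frame from [estimate_dose()] with a
#'   `delivered_dose` column.
#' @return A ggplot object.
#' @export
plot_dose_estimates <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  if (!"delivered_dose" %in% names(estimates)) {
    abort("estimates must carry a delivered_dose column")
  }
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$delivered_dose, y = .data$dose_gy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0.5, linetype = "dotted") +
    ggplot2::geom_abline(slope = 1, intercept = -0.5, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low_gy,
                                          ymax = .data$ci_high_gy)) +
    ggplot2::labs(x = "Delivered dose (Gy)", y = "Estimated dose (Gy)",
                  title = "Dose estimates vs delivered doses") +
    ggplot2::theme_minimal()
}
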