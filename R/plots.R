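#' Bland-Altman plot
#'
#' Difference (test minus criterion) against the per-participant mean of
#' the two methods. The classic variant draws the mean difference and the
#' constant limits of agreement; the Ludbrook variant draws the fitted bias
#' regression with its prediction band.
#'
#' @param object A `"bland_altman"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' sim <- simulate_cohort(n = 304, seed = 1)
#' autoplot(bland_altman(sim$cohort$mvpa_q, sim$cohort$mvpa_accel))
#' @export
#' @method autoplot bland_altman
autoplot.bland_altman <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.4) +
    ggplot2::labs(
      x = "Mean of methods (min/day)",
      y = "Test - criterion (min/day)",
      title = sprintf("Bland-Altman (%s)", object$variant),
      subtitle = sprintf("mean difference %.1f [LoA %.1f; %.1f], bias slope %.3f",
                         object$mean_diff, object$loa_lower, object$loa_upper,
                         object$slope)
    ) +
    ggplot2::theme_minimal()
  if (object$variant == "classic") {
    p + ggplot2::geom_hline(yintercept = object$mean_diff,
                            linetype = "solid") +
      ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                          linetype = "dashed")
  } else {
    p + ggplot2::geom_line(data = object$band,
                           ggplot2::aes(y = .data$bias)) +
      ggplot2::geom_line(data = object$band,
                         ggplot2::aes(y = .data$lower), linetype = "dashed") +
      ggplot2::geom_line(data = object$band,
                         ggplot2::aes(y = .data$upper), linetype = "dashed")
  }
}

#' Plot calibrated and noncalibrated MVPA against the criterion
#'
#' @param cohort Cohort tibble with `mvpa_q`, `mvpa_accel` and (optionally)
#'   `mvpa_calibrated`.
#' @return A ggplot.
#' @export
plot_calibration <- function(cohort) {
  cols <- intersect(c("mvpa_q", "mvpa_calibrated"), names(cohort))
  long <- tidyr::pivot_longer(cohort[c("mvpa_accel", cols)],
                              dplyr::all_of(cols),
                              names_to = "method", values_to = "mvpa")
  long$method <- dplyr::recode(long$method, mvpa_q = "noncalibrated",
                               mvpa_calibrated = "calibrated")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mvpa_accel, y = .data$mvpa)) +
    ggplot2::geom_point(alpha = 0.5, size = 1.2) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Accelerometer MVPA (min/day)",
                  y = "Questionnaire MVPA (min/day)") +
    ggplot2::theme_minimal()
}
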