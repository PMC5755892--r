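#' Agreement plots (regression + Bland-Altman)
#'
#' Two-panel figure: automated versus reference volumes with the OLS line,
#' and the Bland-Altman plot (differences against pair means with bias and
#' limits of agreement).
#'
#' @param object a [paired_volumes()] tibble.
#' @param quantity `"total"` or `"air_free"`.
#' @param loa_multiplier limits-of-agreement multiplier.
#' @param ... unused.
#' @return A patchwork of two ggplot panels.
#' @export
autoplot.paired_volumes <- function(object, quantity = "total",
                                    loa_multiplier = 1.96, ...) {
  fit <- fit_regression(object, quantity)
  ba <- bland_altman(object, quantity, loa_multiplier)
  sub <- object[object$quantity == quantity, , drop = FALSE]
  lab <- if (quantity == "total") "total volume" else "air-free volume"
  p1 <- ggplot2::ggplot(sub, ggplot2::aes(.data$reference_cm3,
                                          .data$automated_cm3)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(paste("reference volume (", cm^3, ")")),
      y = expression(paste("automated volume (", cm^3, ")")),
      subtitle = sprintf("y = %.2fx %+.2f,  R² = %.2f",
                         fit$slope, fit$intercept, fit$r_squared),
      title = paste("Regression,", lab)) +
    ggplot2::theme_minimal()
  ba_df <- tibble::tibble(mean = ba$means, diff = ba$differences)
  p2 <- ggplot2::ggplot(ba_df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = expression(paste("mean of methods (", cm^3, ")")),
      y = expression(paste("automated - reference (", cm^3, ")")),
      subtitle = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                         ba$bias, ba$loa_low, ba$loa_high),
      title = paste("Bland-Altman,", lab)) +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 2)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.paired_volumes
#' @param pairs a [paired_volumes()] tibble.
#' @export
plot_agreement <- function(pairs, quantity = "total",
                           loa_multiplier = 1.96) {
  autoplot.paired_volumes(pairs, quantity, loa_multiplier)
}

#' Bar chart of per-sinus volumes
#'
#' @param object a `sinus_measurements` tibble from [compute_volumes()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sinus_measurements <- function(object, ...) {
  long <- tibble::tibble(
    side = rep(object$side, 2L),
    class = rep(c("air", "involvement"), each = nrow(object)),
    volume_cm3 = c(object$air_volume_cm3, object$involvement_volume_cm3))
  ggplot2::ggplot(long, ggplot2::aes(.data$side, .data$volume_cm3,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(air = "skyblue3",
                                          involvement = "firebrick")) +
    ggplot2::labs(x = NULL,
                  y = expression(paste("volume (", cm^3, ")"))) +
    ggplot2::theme_minimal()
}
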