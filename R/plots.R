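#' Plot a size spectrum
#'
#' Log10 number (and, when present, volume) spectrum against the size-class
#' midpoint; empty classes sit at the -1.0 sentinel.
#'
#' @param object an `agg_spectrum`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot agg_spectrum
#' @export
autoplot.agg_spectrum <- function(object, ...) {
  spec <- log_transform_spectrum(object)
  dat <- spec %>%
    mutate(mid = sqrt(.data$lower * .data$upper)) %>%
    tidyr::pivot_longer(dplyr::any_of(c("log10_n_spec", "log10_nvd")),
                        names_to = "spectrum", values_to = "log10_value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mid, y = .data$log10_value,
                                    colour = .data$spectrum)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "aggregate diameter (mm)",
                  y = "log10 spectrum",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a size~velocity power-law fit
#'
#' Data points with the fitted curve on log-log axes.
#'
#' @param object an `agg_powerfit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot agg_powerfit
#' @export
autoplot.agg_powerfit <- function(object, ...) {
  dgrid <- seq(min(object$data$d), max(object$data$d), length.out = 100)
  curve <- tibble(d = dgrid, u = predict(object, d = dgrid))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$d, y = .data$u)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "aggregate diameter (mm)",
                  y = "settling velocity (m d⁻¹)",
                  subtitle = sprintf("u = %.3g d^%.3g (%s)",
                                     object$a, object$b, object$method)) +
    ggplot2::theme_minimal()
}

#' Plot the remineralization loss curve
#'
#' @param loss tibble from [loss_curve()].
#' @return a ggplot object.
#' @export
plot_loss_curve <- function(loss) {
  ggplot2::ggplot(loss, ggplot2::aes(x = .data$d_mm, y = .data$L_pct_per_m)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "aggregate diameter (mm)",
                  y = "POC respired per meter settled (% m⁻¹)") +
    ggplot2::theme_minimal()
}
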