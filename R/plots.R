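# ggplot2 displays for the main result types. Styling is deliberately
# plain; everything returns a ggplot for further customisation.

#' @export
autoplot.bleaching_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$temperature_c,
                                       .data$fraction_bleached)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Temperature (°C)", y = "Fraction of hosts bleached")
}

#' @export
autoplot.removal_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frac_removed,
                                       .data$frac_remaining)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = paste0("Fraction of ", attr(object, "entity") %||% "entitie",
                             "s removed"),
                  y = "Fraction of nodes remaining")
}

#' @export
autoplot.resistance_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$resistance)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "Resistance R", y = "Replicates")
}

#' @export
autoplot.r50_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$r50)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "R50", y = "Replicates")
}

#' @export
autoplot.ensemble_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "Ensemble mean ± sd")
}

#' Plot an ensemble-averaged bleaching curve with percentile bands
#'
#' @param result A `resistance_result` computed with `keep_curves = TRUE`.
#' @param step,probs Passed to [ensemble_curve()].
#' @return A ggplot.
#' @export
plot_ensemble_curve <- function(result, step = 0.01, probs = c(0.015, 0.985)) {
  grid <- ensemble_curve(result, step, probs)
  ggplot2::ggplot(grid, ggplot2::aes(.data$temperature_c, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "Fraction of hosts bleached")
}
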