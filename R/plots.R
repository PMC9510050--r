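#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 96-context mutational signature
#'
#' Bar chart of the 96 trinucleotide-context fractions, faceted by the six
#' substitution classes in the conventional ordering.
#'
#' @param object A `dnm_spectrum` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dnm_spectrum
#' @export
autoplot.dnm_spectrum <- function(object, ...) {
  d <- object$contexts
  d$context <- factor(d$context, unique(d$context[order(d$class, d$context)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$fraction,
                                  fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~class, scales = "free_x") +
    ggplot2::labs(x = "trinucleotide context", y = "fraction of SNVs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5))
}

#' Plot a parental-age or family-size regression
#'
#' Scatter of the fitted data with the least-squares line and its 95%
#' confidence band.
#'
#' @param object A `dnm_fit` object from [fit_age_trend()],
#'   [family_size_effect()] or [fit_poisson_identity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dnm_fit
#' @export
autoplot.dnm_fit <- function(object, ...) {
  mf <- object$fit$model
  names(mf)[1:2] <- c("response", "predictor")
  ggplot2::ggplot(mf, ggplot2::aes(x = .data$predictor,
                                   y = .data$response)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "steelblue") +
    ggplot2::labs(title = object$model,
                  subtitle = sprintf("slope %.2f (95%% CI %.2f-%.2f)",
                                     object$slope, object$conf_low,
                                     object$conf_high),
                  x = "predictor", y = "DNM count") +
    ggplot2::theme_minimal()
}

#' Plot GC content around DNMs across window sizes
#'
#' @param profile Tibble from [gc_profile()].
#' @return A ggplot object.
#' @export
plot_gc_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$window, y = .data$mean_gc,
                                        colour = .data$variant_class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window size (bases)", y = "mean GC fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
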