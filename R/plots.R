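# ggplot2 views of the main result types

#' Scatter plot of a class regression
#'
#' Gene count against genome size for one functional class, with the
#' fitted least-squares line; focal strains are highlighted so their
#' position relative to the family-wide trend is visible.
#'
#' @inheritParams fit_class_regression
#' @param fit Optional precomputed `regression_fit`.
#' @return A ggplot object.
#' @export
plot_class_regression <- function(metadata, class_counts, class_code,
                                  fit = NULL) {
  fit <- fit %||% fit_class_regression(metadata, class_counts, class_code)
  dat <- dplyr::inner_join(metadata, class_counts[, c("strain_id", class_code)],
                           by = "strain_id")
  dat$count <- dat[[class_code]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$genome_size_mbp, y = .data$count)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_focal), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 name = "focal") +
    ggplot2::labs(
      x = "genome size (Mbp)", y = sprintf("class %s gene count", class_code),
      title = sprintf("class %s: y = %.3f x %+.3f (r2 = %.2f)",
                      class_code, fit$slope, fit$intercept, fit$r2)) +
    ggplot2::theme_minimal()
}

#' Bar chart of class regression slopes
#'
#' @param fits Tibble from [fit_class_regressions()].
#' @return A ggplot object.
#' @export
plot_class_slopes <- function(fits) {
  ranked <- rank_classes(fits)
  ranked$class <- factor(ranked$class, levels = rev(ranked$class))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$slope, y = .data$class)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "regression gradient (genes per Mbp)", y = "COG class") +
    ggplot2::theme_minimal()
}

#' @describeIn chance_model Plot f(x) on a log scale with the peak marked.
#' @param object,x A `chance_model`.
#' @param ... Ignored.
#' @export
autoplot.chance_model <- function(object, ...) {
  curve <- chance_factors(seq(0.001, 0.999, by = 0.001), object)
  pk <- find_chance_peak(object)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = pk$x_peak, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "per-species loss probability x", y = "f(x)",
      title = sprintf("chance model peak: f(%.3f) = %.3g", pk$x_peak, pk$f_peak)) +
    ggplot2::theme_minimal()
}

#' Plot a marker screen result
#'
#' Focal versus other presence counts, coloured by screen category.
#'
#' @param screen_result Tibble from [screen_markers()].
#' @return A ggplot object.
#' @export
plot_screen <- function(screen_result) {
  ggplot2::ggplot(screen_result,
                  ggplot2::aes(x = .data$other_count, y = .data$focal_count,
                               colour = .data$category)) +
    ggplot2::geom_jitter(width = 0.3, height = 0.3, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(specific = "red",
                                            missing = "blue",
                                            neither = "grey70")) +
    ggplot2::labs(x = "presence in other strains",
                  y = "presence in focal strains") +
    ggplot2::theme_minimal()
}
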