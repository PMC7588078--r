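#' Volcano plot of a screen comparison
#'
#' Epsilon phenotype score against `-log10(p)`, hits colored by regulator
#' sign.
#'
#' @param object A `screen_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_comparison
#' @export
autoplot.screen_comparison <- function(object, ...) {
  dat <- tidy(object)
  dat$class <- ifelse(dat$hit, dat$regulator_sign, "not a hit")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epsilon,
                                    y = .data$neg_log10_p,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166AC", negative = "#B2182B",
                 `not a hit` = "grey60"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "epsilon (mean log2 fold change, 3 most extreme sgRNAs)",
      y = expression(-log[10](italic(p))),
      title = paste("Gene enrichment,",
                    paste(object$comparison, collapse = " vs "))
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plots for every comparison of a screen analysis
#'
#' @param object A `screen_analysis`.
#' @param ... Unused.
#' @return A ggplot object faceted by comparison.
#' @method autoplot screen_analysis
#' @export
autoplot.screen_analysis <- function(object, ...) {
  dat <- tidy(object)
  dat$class <- ifelse(dat$hit, dat$regulator_sign, "not a hit")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$epsilon,
                                    y = .data$neg_log10_p,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166AC", negative = "#B2182B",
                 `not a hit` = "grey60"),
      name = NULL
    ) +
    ggplot2::labs(x = "epsilon", y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Reporter-fluorescence histogram of a simulated population with its gates
#'
#' @param population Cell tibble from [simulate_cells()].
#' @param fractions Optional `sorted_fractions` whose valley is drawn.
#' @param bins Histogram bins (default 128).
#' @return A ggplot object.
#' @export
plot_fluorescence <- function(population, fractions = NULL, bins = 128) {
  dat <- tibble(log10_fluorescence = log10(population$fluorescence))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$log10_fluorescence)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "log10 reporter fluorescence", y = "cells") +
    ggplot2::theme_minimal()
  if (!is.null(fractions)) {
    p <- p + ggplot2::geom_vline(xintercept = fractions$valley,
                                 linetype = "dashed", colour = "#B2182B")
  }
  p
}
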