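#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screen comparison into per-gene rows
#'
#' @param x A `screen_comparison` from [analyze_comparison()].
#' @param ... Unused.
#' @return The gene-score tibble with `neg_log10_p`, the `hit` flag at the
#'   selected threshold, `regulator_sign` (NA for non-hits) and `comparison`
#'   appended.
#' @method tidy screen_comparison
#' @export
tidy.screen_comparison <- function(x, ...) {
  thr <- x$threshold$threshold
  x$scores |>
    mutate(
      neg_log10_p = -log10(.data$p_value),
      hit = abs(.data$hit_strength) >= thr,
      regulator_sign = dplyr::case_when(
        !.data$hit ~ NA_character_,
        .data$epsilon > 0 ~ "positive",
        .default = "negative"
      ),
      comparison = paste0(x$comparison[1], "_vs_", x$comparison[2])
    )
}

#' One-row summary of a screen comparison
#'
#' @inheritParams tidy.screen_comparison
#' @return A one-row tibble: `comparison`, `n_targets`, `n_quasi`,
#'   `threshold`, `achieved_fdr`, `target_fdr`, `n_hits`, `n_positive`,
#'   `n_negative`.
#' @method glance screen_comparison
#' @export
glance.screen_comparison <- function(x, ...) {
  tibble(
    comparison = paste0(x$comparison[1], "_vs_", x$comparison[2]),
    n_targets = nrow(x$scores),
    n_quasi = nrow(x$quasi_scores),
    threshold = x$threshold$threshold,
    achieved_fdr = x$threshold$achieved_fdr,
    target_fdr = x$threshold$target_fdr,
    n_hits = x$threshold$n_hits,
    n_positive = sum(x$hits$regulator_sign == "positive"),
    n_negative = sum(x$hits$regulator_sign == "negative")
  )
}

#' Tidy all comparisons of a screen analysis
#'
#' @param x A `screen_analysis` from [run_all_comparisons()].
#' @param ... Unused.
#' @return Row-bound [tidy.screen_comparison()] tibbles.
#' @method tidy screen_analysis
#' @export
tidy.screen_analysis <- function(x, ...) {
  bind_rows(lapply(unclass(x), tidy))
}

#' Per-comparison summaries of a screen analysis
#'
#' @inheritParams tidy.screen_analysis
#' @return One [glance.screen_comparison()] row per comparison.
#' @method glance screen_analysis
#' @export
glance.screen_analysis <- function(x, ...) {
  bind_rows(lapply(unclass(x), glance))
}
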