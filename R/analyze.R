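#' Analyze one pairwise fraction comparison end to end
#'
#' Scores every gene for the chosen pair of sorted fractions, builds and
#' scores a seeded quasi-gene null, selects the hit-strength cutoff at the
#' target empirical FDR, and calls hits. This is the unit the three-fraction
#' screen analysis repeats per comparison.
#'
#' @inheritParams score_genes
#' @inheritParams find_threshold
#' @param n_quasi Quasi-genes for the null (default 10 per real target).
#' @param seed Seed for the quasi-gene draw.
#' @return An object of class `screen_comparison`: a list with `scores`,
#'   `quasi_scores`, `threshold` (an `fdr_threshold` row), `hits`, and
#'   `comparison`. Use [tidy()][tidy.screen_comparison()] /
#'   [glance()][glance.screen_comparison()] / `autoplot()` on it.
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 15, n_ntc = 25,
#'                                          coverage = 20, depth = 2e4),
#'                        seed = 1)
#' cmp <- analyze_comparison(sim$counts, sim$library, "low", "high", seed = 1)
#' glance(cmp)
analyze_comparison <- function(counts, library, numerator = "low",
                               denominator = "high", target_fdr = 0.10,
                               n_quasi = NULL, pseudocount = 1, k = 3L,
                               center = TRUE, seed = 1L) {
  library <- validate_library(library)
  scores <- score_genes(counts, library, numerator, denominator,
                        pseudocount = pseudocount, k = k, center = center)
  quasi <- make_quasi_genes(library, n_quasi = n_quasi, seed = seed)
  quasi_scores <- score_quasi_genes(counts, library, quasi, numerator,
                                    denominator, pseudocount = pseudocount,
                                    k = k, center = center)
  threshold <- find_threshold(scores, quasi_scores, target_fdr = target_fdr)
  hits <- call_hits(scores, threshold, comparison = c(numerator, denominator))
  structure(
    list(scores = scores, quasi_scores = quasi_scores, threshold = threshold,
         hits = hits, comparison = c(numerator, denominator)),
    class = "screen_comparison"
  )
}

#' @export
print.screen_comparison <- function(x, ...) {
  cat("Sorted-screen comparison", paste(x$comparison, collapse = " vs "),
      "\n")
  cat(" ", nrow(x$scores), "targets,", nrow(x$quasi_scores), "quasi-genes\n")
  cat("  |hit strength| threshold", format(x$threshold$threshold, digits = 4),
      "at target FDR", x$threshold$target_fdr, "->", x$threshold$n_hits,
      "hits\n")
  invisible(x)
}

#' Run the three pairwise comparisons of a sorted screen
#'
#' Analyses the three pairwise comparisons of the low/medium/high count
#' columns — `low_vs_high`, `medium_vs_high` and `low_vs_medium` — each with
#' its own quasi-gene null derived from a shared seed base. The numerator is
#' always the lower-fluorescence fraction of the pair, so a positive
#' regulator carries a positive epsilon in every comparison.
#'
#' @inheritParams analyze_comparison
#' @return An object of class `screen_analysis`: a named list of
#'   `screen_comparison` objects.
#' @export
run_all_comparisons <- function(counts, library, target_fdr = 0.10,
                                n_quasi = NULL, pseudocount = 1, k = 3L,
                                center = TRUE, seed = 1L) {
  missing <- setdiff(c("low", "medium", "high"), names(counts))
  if (length(missing) > 0) {
    stop_sortscreen(
      paste0("count matrix lacks fraction column(s): ",
             paste(missing, collapse = ", ")),
      class = "sortscreen_config_error"
    )
  }
  pairs <- list(
    low_vs_high = c("low", "high"),
    medium_vs_high = c("medium", "high"),
    low_vs_medium = c("low", "medium")
  )
  seeds <- split_seed(seed, names(pairs))
  out <- purrr::imap(pairs, function(pair, name) {
    analyze_comparison(counts, library, pair[1], pair[2],
                       target_fdr = target_fdr, n_quasi = n_quasi,
                       pseudocount = pseudocount, k = k, center = center,
                       seed = seeds[[name]])
  })
  structure(out, class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("Sorted-screen analysis of", length(x), "pairwise comparisons\n")
  for (cmp in x) {
    cat(sprintf("  %-16s %4d hits (threshold %s)\n",
                paste(cmp$comparison, collapse = " vs "),
                cmp$threshold$n_hits,
                format(cmp$threshold$threshold, digits = 4)))
  }
  invisible(x)
}
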