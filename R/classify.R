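#' Classify hits into high-confidence and putative sets
#'
#' Applies the three-fraction confidence logic: genes hit in the low-vs-high
#' comparison are "high_confidence"; genes hit in a comparison involving the
#' medium fraction but not in low-vs-high are "putative". A gene hit in
#' several comparisons is classified once, with high confidence taking
#' precedence, so the two classes partition the hit genes.
#'
#' @param x Either a [run_all_comparisons()] result, or the low-vs-high hit
#'   table (tibble with a `target` column, or a character vector of genes)
#'   with the two medium-comparison hit tables passed via `medium_high` and
#'   `low_medium`.
#' @param medium_high,low_medium Hit tables (or gene vectors) of the two
#'   comparisons involving the medium fraction (ignored when `x` is a
#'   `screen_analysis`).
#' @param ... Unused.
#' @return A tibble with one row per hit gene: `gene`, `confidence_class`,
#'   and — when the inputs carry them — `epsilon`, `p_value`,
#'   `hit_strength`, `regulator_sign`, `comparison` taken from the defining
#'   comparison (low-vs-high for high-confidence genes, the strongest medium
#'   comparison otherwise). The number of genes shared between the
#'   low-vs-high and medium hit sets is attached as attribute `n_shared`.
#' @export
#' @examples
#' classify_hits(c("ADRB2", "NUP93"), medium_high = c("ADRB2", "HRAS"),
#'               low_medium = "MICAL3")
classify_hits <- function(x, medium_high = NULL, low_medium = NULL, ...) {
  if (inherits(x, "screen_analysis")) {
    low_high <- x$low_vs_high$hits
    medium_high <- x$medium_vs_high$hits
    low_medium <- x$low_vs_medium$hits
  } else {
    low_high <- x
  }
  a <- as_hit_table(low_high)
  b <- bind_rows(as_hit_table(medium_high), as_hit_table(low_medium))
  # one row per gene within each set, keeping its strongest record
  a <- strongest_per_gene(a)
  b <- strongest_per_gene(b)
  shared <- intersect(a$gene, b$gene)
  out <- bind_rows(
    mutate(a, confidence_class = "high_confidence"),
    mutate(filter(b, !.data$gene %in% a$gene),
           confidence_class = "putative")
  )
  attr(out, "n_shared") <- length(shared)
  out
}

as_hit_table <- function(h) {
  if (is.null(h)) {
    return(tibble(gene = character()))
  }
  if (!is.data.frame(h)) {
    return(tibble(gene = as.character(h)))
  }
  h <- as_tibble(h)
  if (!"gene" %in% names(h)) {
    if (!"target" %in% names(h)) {
      stop_sortscreen("hit tables need a target or gene column",
                      class = "sortscreen_validation_error")
    }
    h <- rename(h, gene = "target")
  }
  h
}

strongest_per_gene <- function(h) {
  if (!"hit_strength" %in% names(h)) {
    return(distinct(h, .data$gene, .keep_all = TRUE))
  }
  h |>
    arrange(dplyr::desc(abs(.data$hit_strength))) |>
    distinct(.data$gene, .keep_all = TRUE)
}

#' Collapse TSS-level scores to one row per gene
#'
#' Libraries target transcription start sites; a gene with several TSSs gets
#' several score rows. Per gene the TSS row with the largest absolute hit
#' strength is kept (ties broken by the smallest `tss_id`).
#'
#' @param scores A gene-score tibble with `target` (gene) and `tss_id`
#'   columns.
#' @return The collapsed tibble, one row per gene.
#' @export
collapse_tss_to_gene <- function(scores) {
  if (!all(c("target", "tss_id") %in% names(scores))) {
    stop_sortscreen("scores need target and tss_id columns",
                    class = "sortscreen_config_error")
  }
  scores |>
    arrange(dplyr::desc(abs(.data$hit_strength)), .data$tss_id) |>
    distinct(.data$target, .keep_all = TRUE) |>
    arrange(.data$target)
}

#' Hypergeometric test of hit-set overlap
#'
#' One-sided Fisher's exact test for enrichment of the overlap of two gene
#' sets drawn from a common universe: the upper hypergeometric tail
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, |A|, |B|)`, evaluated
#' in log space so that extremely small p-values keep full accuracy.
#'
#' @param set_a,set_b Character vectors of genes.
#' @param universe_size Size of the gene universe both sets were drawn from.
#' @return A one-row tibble: `overlap`, `n_a`, `n_b`, `universe_size`,
#'   `p_value`, `log10_p`.
#' @export
#' @examples
#' overlap_test(letters[1:5], letters[1:5], universe_size = 20)
overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  n_a <- length(set_a)
  n_b <- length(set_b)
  if (n_a > universe_size || n_b > universe_size) {
    stop_sortscreen("set sizes cannot exceed the universe size",
                    class = "sortscreen_validation_error")
  }
  k <- length(intersect(set_a, set_b))
  log_p <- phyper(k - 1, n_a, universe_size - n_a, n_b,
                  lower.tail = FALSE, log.p = TRUE)
  tibble(overlap = k, n_a = n_a, n_b = n_b, universe_size = universe_size,
         p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Write a volcano-plot table
#'
#' Emits the per-gene table behind a volcano plot — epsilon against
#' `-log10(p)` — with the hit flag and regulator sign at the given
#' hit-strength threshold, ordered by gene, as a TSV.
#'
#' @param scores Gene-score tibble for one comparison.
#' @param threshold Absolute hit-strength cutoff (an `fdr_threshold` row or
#'   a number).
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_volcano_table <- function(scores, threshold, path) {
  thr <- if (is.data.frame(threshold)) threshold$threshold else
    as.numeric(threshold)
  tab <- scores |>
    mutate(
      neg_log10_p = -log10(.data$p_value),
      hit = abs(.data$hit_strength) >= thr,
      regulator_sign = dplyr::case_when(
        !.data$hit ~ NA_character_,
        .data$epsilon > 0 ~ "positive",
        .default = "negative"
      )
    ) |>
    select("target", "tss_id", "epsilon", "neg_log10_p", "hit_strength",
           "hit", "regulator_sign") |>
    arrange(.data$target, .data$tss_id)
  readr::write_tsv(tab, path)
  invisible(tab)
}
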