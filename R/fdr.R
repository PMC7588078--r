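#' Draw negative-control quasi-genes
#'
#' Builds the empirical null for hit calling: pseudo-genes assembled by
#' sampling `group_size` (default 5) non-targeting control sgRNAs with
#' replacement from the same library, so a quasi-gene may contain repeats.
#' Scored like real genes ([score_quasi_genes()]), their hit-strength
#' distribution calibrates the false discovery rate. Quasi-genes are
#' allocated across libraries in proportion to each library's number of real
#' targets.
#'
#' @param library Library tibble (must contain NTCs).
#' @param n_quasi Number of quasi-genes; default 10 per real target. A large
#'   multiple of the target count keeps the extreme tail of the null stable
#'   (see the package vignette).
#' @param group_size sgRNAs per quasi-gene (default 5).
#' @param seed RNG seed; a fixed seed makes the whole hit list reproducible.
#' @return A tibble of class `quasi_gene_set` in long form: `quasi_id`,
#'   `library_id`, `sgrna_id`, with `group_size` rows per quasi-gene.
#' @export
make_quasi_genes <- function(library, n_quasi = NULL, group_size = 5L,
                             seed = NULL) {
  library <- validate_library(library)
  ntc <- filter(library, is_ntc(library))
  if (nrow(ntc) == 0) {
    stop_sortscreen("library has no non-targeting controls",
                    class = "sortscreen_config_error")
  }
  targets <- library |>
    filter(!is_ntc(library)) |>
    distinct(.data$library_id, .data$target, .data$tss_id) |>
    dplyr::count(.data$library_id, name = "n_targets")
  if (is.null(n_quasi)) n_quasi <- 10L * sum(targets$n_targets)
  n_quasi <- as.integer(n_quasi)
  if (n_quasi == 0) {
    return(structure(
      tibble(quasi_id = character(), library_id = character(),
             sgrna_id = character()),
      class = c("quasi_gene_set", "tbl_df", "tbl", "data.frame")
    ))
  }
  # allocate across libraries proportionally to their real target counts
  alloc <- floor(n_quasi * targets$n_targets / sum(targets$n_targets))
  rem <- n_quasi - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  with_seed_(seed, {
    out <- purrr::map2(targets$library_id, alloc, function(lib_id, k) {
      if (k == 0) return(NULL)
      pool <- ntc$sgrna_id[ntc$library_id == lib_id]
      tibble(
        quasi_id = rep(sprintf("quasi_%s_%06d", lib_id, seq_len(k)),
                       each = group_size),
        library_id = lib_id,
        sgrna_id = sample(pool, k * group_size, replace = TRUE)
      )
    })
    structure(bind_rows(out),
              class = c("quasi_gene_set", "tbl_df", "tbl", "data.frame"))
  })
}

#' Score quasi-genes exactly like real genes
#'
#' Runs the [score_genes()] pipeline with the quasi-gene groups in place of
#' the gene/TSS groups: per quasi-gene, epsilon over its member fold changes
#' and a Mann-Whitney p-value against the library's NTC fold changes. As for
#' a real gene — whose sgRNAs are never part of its own reference — the
#' quasi-gene's member sgRNAs are excluded from its reference set, which
#' keeps real and quasi scores exchangeable on a null screen.
#'
#' @inheritParams score_genes
#' @param quasi A `quasi_gene_set` from [make_quasi_genes()].
#' @return A gene-score tibble (`target` holds the quasi-gene id).
#' @export
score_quasi_genes <- function(counts, library, quasi, numerator, denominator,
                              pseudocount = 1, k = 3L, center = TRUE) {
  if (nrow(quasi) == 0) {
    return(tibble(target = character(), tss_id = character(),
                  library_id = character(), epsilon = numeric(),
                  p_value = numeric(), hit_strength = numeric(),
                  n_sgrnas = integer()))
  }
  bad <- setdiff(quasi$sgrna_id, library$sgrna_id[is_ntc(library)])
  if (length(bad) > 0) {
    stop_sortscreen("quasi-gene members must be NTC sgRNAs",
                    class = "sortscreen_validation_error")
  }
  library <- validate_library(library)
  freqs <- normalize_counts(counts, library, pseudocount)
  phen <- sgrna_log2fc(freqs, numerator, denominator)
  if (center) phen <- center_to_ntc(phen, library)
  score_lfc_groups(phen, library, k = k, groups = quasi)
}

hit_strengths <- function(scores) {
  if (is.data.frame(scores)) scores$hit_strength else as.numeric(scores)
}

#' Empirical false discovery rate at a hit-strength threshold
#'
#' The exceedance-ratio estimator over the real and quasi-gene hit-strength
#' distributions:
#' `FDR(t) = (Q(t) / N_Q) / (R(t) / N_R)` with `Q(t)`, `R(t)` the numbers of
#' quasi and real scores of absolute hit strength at least `t`. Defined as 0
#' when no quasi-gene passes; an error when no real gene passes.
#'
#' @param real_scores,quasi_scores Gene-score tibbles (or bare numeric
#'   hit-strength vectors).
#' @param threshold Threshold `t >= 0` on absolute hit strength.
#' @return The FDR estimate (may exceed 1 on null data).
#' @export
#' @examples
#' empirical_fdr(1:8, 1:4, threshold = 3.5)  # (1/4) / (5/8) = 0.4
empirical_fdr <- function(real_scores, quasi_scores, threshold) {
  r <- abs(hit_strengths(real_scores))
  q <- abs(hit_strengths(quasi_scores))
  if (length(r) == 0 || length(q) == 0) {
    stop_sortscreen("both score sets must be non-empty",
                    class = "sortscreen_config_error")
  }
  if (threshold < 0) {
    stop_sortscreen("threshold must be >= 0",
                    class = "sortscreen_config_error")
  }
  R <- sum(r >= threshold)
  Q <- sum(q >= threshold)
  if (R == 0) {
    stop_sortscreen("no real gene reaches the threshold",
                    class = "sortscreen_no_passing_genes")
  }
  if (Q == 0) return(0)
  (Q / length(q)) / (R / length(r))
}

#' Choose the hit-strength cutoff for a target FDR
#'
#' Scans the attained real absolute hit-strength values and returns the
#' smallest one `t` such that the empirical FDR stays below `target_fdr` at
#' `t` and at every larger attained value (a monotone acceptance rule: the
#' accepted region is a single upper tail). If no value qualifies the
#' threshold is `+Inf` and there are no hits.
#'
#' @inheritParams empirical_fdr
#' @param target_fdr FDR bound (default 0.10, the conventional screen
#'   cutoff).
#' @return A one-row tibble of class `fdr_threshold`: `threshold`,
#'   `achieved_fdr` (`NA` when nothing passes), `target_fdr`, `n_hits`,
#'   `n_real`, `n_quasi`.
#' @export
#' @examples
#' find_threshold(1:8, 1:4, target_fdr = 0.1)  # threshold 5, 4 hits
find_threshold <- function(real_scores, quasi_scores, target_fdr = 0.10) {
  r <- abs(hit_strengths(real_scores))
  q <- abs(hit_strengths(quasi_scores))
  if (length(r) == 0 || length(q) == 0) {
    stop_sortscreen("both score sets must be non-empty",
                    class = "sortscreen_config_error")
  }
  cand <- sort(unique(r))
  q_sorted <- sort(q)
  # counts with |value| >= t, via binary search on the sorted vectors
  Q <- length(q) - findInterval(cand, q_sorted, left.open = TRUE)
  R <- length(r) - findInterval(cand, sort(r), left.open = TRUE)
  fdr <- (Q / length(q)) / (R / length(r))
  ok <- rev(cumprod(rev(fdr < target_fdr))) > 0
  if (!any(ok)) {
    thr <- Inf
    achieved <- NA_real_
    n_hits <- 0L
  } else {
    i <- which(ok)[1]
    thr <- cand[i]
    achieved <- fdr[i]
    n_hits <- as.integer(R[i])
  }
  structure(
    tibble(threshold = thr, achieved_fdr = achieved,
           target_fdr = target_fdr, n_hits = n_hits,
           n_real = length(r), n_quasi = length(q)),
    class = c("fdr_threshold", "tbl_df", "tbl", "data.frame")
  )
}

#' Call hits at a chosen threshold
#'
#' Keeps the genes whose absolute hit strength reaches the threshold and
#' assigns the regulator sign. Scores must have been computed with the
#' lower-fluorescence fraction as the numerator: then `epsilon > 0` means
#' the gene's sgRNAs are enriched in the lower fraction — silencing lowers
#' reporter expression, a positive regulator — and `epsilon < 0` a negative
#' regulator.
#'
#' @param scores Gene-score tibble for one comparison.
#' @param threshold_result An `fdr_threshold` row from [find_threshold()],
#'   or a single number.
#' @param comparison Character pair `c(numerator, denominator)` recorded in
#'   the output.
#' @return The passing rows with `regulator_sign` (`"positive"` /
#'   `"negative"`) and `comparison` (`"<num>_vs_<den>"`) columns appended.
#' @export
call_hits <- function(scores, threshold_result,
                      comparison = c("low", "high")) {
  thr <- if (is.data.frame(threshold_result)) {
    threshold_result$threshold
  } else {
    as.numeric(threshold_result)
  }
  if (thr == 0) {
    rlang::warn("threshold 0 admits genes with hit strength 0, whose sign is undefined",
                class = "sortscreen_zero_threshold")
  }
  scores |>
    filter(abs(.data$hit_strength) >= thr) |>
    mutate(
      regulator_sign = ifelse(.data$epsilon > 0, "positive", "negative"),
      comparison = paste0(comparison[1], "_vs_", comparison[2])
    ) |>
    arrange(dplyr::desc(abs(.data$hit_strength)))
}
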