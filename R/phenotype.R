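#' Normalize sgRNA counts to within-sample frequencies
#'
#' Converts counts to pseudocounted relative frequencies,
#' `freq(i, s) = (count(i, s) + pseudocount) / sum_j (count(j, s) + pseudocount)`,
#' computed separately within each library (frequencies in one sample of one
#' library sum to 1). The pseudocount must be positive so that log fold
#' changes stay finite for sgRNAs with zero reads.
#'
#' @param counts Count tibble (`sgrna_id` plus sample columns).
#' @param library Library tibble; supplies the library membership and the
#'   complete row set (missing sgRNAs are zero-filled).
#' @param pseudocount Reads added to every count (default 1).
#' @return A tibble `sgrna_id`, `library_id`, then one frequency column per
#'   sample.
#' @export
normalize_counts <- function(counts, library, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop_sortscreen("pseudocount must be > 0",
                    class = "sortscreen_config_error")
  }
  counts <- validate_counts(counts, library)
  samples <- setdiff(names(counts), "sgrna_id")
  counts |>
    left_join(select(library, "sgrna_id", "library_id"), by = "sgrna_id") |>
    group_by(.data$library_id) |>
    mutate(across(all_of(samples),
                  ~ (.x + pseudocount) / sum(.x + pseudocount))) |>
    ungroup() |>
    select("sgrna_id", "library_id", all_of(samples))
}

#' Per-sgRNA log2 fold change between two sorted fractions
#'
#' `lfc_i = log2(freq_i[numerator] / freq_i[denominator])`. With the
#' pseudocounted frequencies of [normalize_counts()] every value is finite.
#' By convention the numerator is the lower-fluorescence fraction of the
#' pair, so that sgRNAs silencing a positive regulator of the reporter get
#' positive fold changes.
#'
#' @param freqs Frequency tibble from [normalize_counts()].
#' @param numerator,denominator Sample (fraction) names.
#' @return A tibble `sgrna_id`, `library_id`, `lfc`, with the comparison
#'   recorded in the `"comparison"` attribute.
#' @export
sgrna_log2fc <- function(freqs, numerator, denominator) {
  for (s in c(numerator, denominator)) {
    if (!s %in% names(freqs)) {
      stop_sortscreen(paste0("sample not present: ", s),
                      class = "sortscreen_config_error")
    }
  }
  if (identical(numerator, denominator)) {
    stop_sortscreen("numerator and denominator must differ",
                    class = "sortscreen_config_error")
  }
  out <- tibble(
    sgrna_id = freqs$sgrna_id,
    library_id = freqs$library_id,
    lfc = log2(freqs[[numerator]] / freqs[[denominator]])
  )
  attr(out, "comparison") <- c(numerator, denominator)
  out
}

#' Center sgRNA fold changes on the non-targeting controls
#'
#' Subtracts, within each library, the median fold change of that library's
#' non-targeting controls from every sgRNA, so the NTC median of the result
#' is zero. Centering is idempotent.
#'
#' @param phenotypes Tibble from [sgrna_log2fc()].
#' @param library Library tibble (identifies the NTC rows).
#' @return The tibble with `lfc` centered.
#' @export
center_to_ntc <- function(phenotypes, library) {
  ntc_ids <- library$sgrna_id[is_ntc(library)]
  if (length(ntc_ids) == 0) {
    stop_sortscreen("library has no non-targeting controls to center on",
                    class = "sortscreen_config_error")
  }
  comparison <- attr(phenotypes, "comparison")
  out <- phenotypes |>
    group_by(.data$library_id) |>
    mutate(lfc = .data$lfc -
             median(.data$lfc[.data$sgrna_id %in% ntc_ids])) |>
    ungroup()
  if (any(is.na(out$lfc))) {
    stop_sortscreen("a library lacks NTCs; cannot center",
                    class = "sortscreen_config_error")
  }
  attr(out, "comparison") <- comparison
  out
}

#' Epsilon phenotype score of one gene
#'
#' The gene-level knockdown phenotype: the signed mean of the `k` sgRNAs
#' (default 3) with the largest absolute NTC-centered log2 fold change. With
#' fewer than `k` sgRNAs all of them are averaged. Ties in absolute value
#' are broken by ascending sgRNA identifier so the score is deterministic.
#'
#' @param lfc Centered log2 fold changes of the gene's sgRNAs.
#' @param k Number of extreme sgRNAs to average (default 3).
#' @param ids Optional sgRNA identifiers used for tie-breaking (defaults to
#'   input order).
#' @return The epsilon score (a single number).
#' @export
#' @examples
#' gene_epsilon(c(-3.0, -2.5, 0.1, -0.2, 0.05))  # mean of -3.0, -2.5, -0.2
gene_epsilon <- function(lfc, k = 3L, ids = NULL) {
  if (length(lfc) == 0) {
    stop_sortscreen("gene has no sgRNA fold changes",
                    class = "sortscreen_config_error")
  }
  if (k < 1) {
    stop_sortscreen("k must be >= 1", class = "sortscreen_config_error")
  }
  if (is.null(ids)) ids <- seq_along(lfc)
  ord <- order(-abs(lfc), ids)
  mean(lfc[ord[seq_len(min(k, length(lfc)))]])
}

#' Mann-Whitney U p-value of a gene against the non-targeting controls
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the gene's sgRNA fold
#' changes against the full NTC fold-change distribution. The exact null
#' distribution of U is used when the smaller sample has at most 8 values
#' and the combined sample has no ties; otherwise the normal approximation
#' with tie correction (no continuity correction) is used. The p-value is
#' clamped to (0, 1].
#'
#' @param gene_lfc Centered fold changes of the gene's sgRNAs.
#' @param ntc_lfc Centered fold changes of all NTCs in the same library.
#' @return The two-sided p-value.
#' @export
gene_pvalue <- function(gene_lfc, ntc_lfc) {
  if (length(gene_lfc) == 0 || length(ntc_lfc) == 0) {
    stop_sortscreen("both value sets must be non-empty",
                    class = "sortscreen_config_error")
  }
  mw_pvalue(gene_lfc, sort(ntc_lfc))
}

# exact-CDF cache: pwilcox(0:(n*m), n, m) per (n, m)
.mw_cache <- new.env(parent = emptyenv())

mw_exact_cdf <- function(n, m) {
  key <- paste0(n, ",", m)
  if (is.null(.mw_cache[[key]])) {
    .mw_cache[[key]] <- pwilcox(0:(n * m), n, m)
  }
  .mw_cache[[key]]
}

# core Mann-Whitney p-value; `ntc_sorted` must be pre-sorted
mw_pvalue <- function(x, ntc_sorted) {
  n <- length(x)
  m <- length(ntc_sorted)
  n_lt <- findInterval(x, ntc_sorted, left.open = TRUE)
  n_le <- findInterval(x, ntc_sorted)
  u <- sum(n_lt) + 0.5 * sum(n_le - n_lt)
  ties <- any(n_le > n_lt) || anyDuplicated(x) > 0 ||
    anyDuplicated(ntc_sorted) > 0
  if (!ties && min(n, m) <= 8) {
    cdf <- mw_exact_cdf(n, m)
    u <- as.integer(round(u))
    p <- if (u > n * m / 2) 1 - cdf[u] else cdf[u + 1]
    p <- min(2 * p, 1)
  } else {
    nn <- n + m
    tie_sizes <- table(c(x, ntc_sorted))
    sigma2 <- (n * m / 12) *
      ((nn + 1) - sum(tie_sizes^3 - tie_sizes) / (nn * (nn - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u - n * m / 2) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Score every gene of a screen for one fraction comparison
#'
#' The per-gene pipeline of the screen analysis: normalize counts to
#' frequencies within each library, compute per-sgRNA log2 fold changes for
#' the chosen pair of fractions, center them on the library's non-targeting
#' controls, then per transcription-start-site target compute the epsilon
#' phenotype score ([gene_epsilon()]), the Mann-Whitney p-value against all
#' the library's NTCs ([gene_pvalue()]) and the hit strength
#' `epsilon * -log10(p)`. NTC sgRNAs serve as the centering and test
#' reference but are not scored as genes.
#'
#' @inheritParams normalize_counts
#' @inheritParams sgrna_log2fc
#' @param k Extreme sgRNAs averaged into epsilon (default 3).
#' @param center Center fold changes on the NTC median first (default TRUE).
#' @return A tibble with one row per target: `target`, `tss_id`,
#'   `library_id`, `epsilon`, `p_value`, `hit_strength`, `n_sgrnas`, ordered
#'   by library, target and TSS.
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 10, n_ntc = 20,
#'                                          coverage = 20, depth = 1e4),
#'                        seed = 1)
#' score_genes(sim$counts, sim$library, "low", "high")
score_genes <- function(counts, library, numerator, denominator,
                        pseudocount = 1, k = 3L, center = TRUE) {
  library <- validate_library(library)
  freqs <- normalize_counts(counts, library, pseudocount)
  phen <- sgrna_log2fc(freqs, numerator, denominator)
  if (center) phen <- center_to_ntc(phen, library)
  score_lfc_groups(phen, library, k = k)
}

# shared by score_genes and score_quasi_genes: per-library NTC reference,
# then epsilon/p/hit-strength per target group. Quasi-gene members are drawn
# from the NTCs, so — like a real gene, whose sgRNAs are never part of its
# reference — each quasi-gene's member sgRNAs are excluded from its own
# Mann-Whitney reference set.
score_lfc_groups <- function(phen, library, k = 3L, groups = NULL) {
  lfc <- setNames(phen$lfc, phen$sgrna_id)
  out <- vector("list", length(unique(library$library_id)))
  li <- 0L
  for (lib_id in unique(library$library_id)) {
    lib <- filter(library, .data$library_id == lib_id)
    ntc_ids <- lib$sgrna_id[is_ntc(lib)]
    ntc_vals <- unname(lfc[ntc_ids])
    ntc_sorted <- sort(ntc_vals)
    if (is.null(groups)) {
      members <- filter(lib, !is_ntc(lib)) |>
        group_by(.data$target, .data$tss_id) |>
        summarise(sgrna_ids = list(.data$sgrna_id), .groups = "drop")
    } else {
      members <- filter(groups, .data$library_id == lib_id) |>
        group_by(.data$quasi_id) |>
        summarise(sgrna_ids = list(.data$sgrna_id), .groups = "drop") |>
        rename(target = "quasi_id") |>
        mutate(tss_id = NA_character_)
    }
    eps <- p <- numeric(nrow(members))
    n_sg <- integer(nrow(members))
    for (i in seq_len(nrow(members))) {
      ids <- members$sgrna_ids[[i]]
      v <- unname(lfc[ids])
      ref <- if (is.null(groups)) {
        ntc_sorted
      } else {
        sort(ntc_vals[!ntc_ids %in% ids])
      }
      eps[i] <- gene_epsilon(v, k = k, ids = ids)
      p[i] <- mw_pvalue(v, ref)
      n_sg[i] <- length(ids)
    }
    li <- li + 1L
    out[[li]] <- tibble(
      target = members$target, tss_id = members$tss_id,
      library_id = lib_id, epsilon = eps, p_value = p,
      hit_strength = eps * (-log10(p)), n_sgrnas = n_sg
    )
  }
  bind_rows(out) |> arrange(.data$library_id, .data$target, .data$tss_id)
}
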