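#' Configuration of a simulated sorted reporter screen
#'
#' Collects the knobs of the generative model. Reporter fluorescence is a
#' two-component lognormal mixture on the log10 scale: a small left-shifted
#' peak of non-responding cells around `mu_off` (mixture weight `pi_off`) and
#' a large right-shifted peak of responding cells around `mu_induced`, each
#' with within-peak standard deviation `sigma`. Silencing a regulator gene
#' shifts a responding cell's mean by the gene's effect size scaled by the
#' per-sgRNA knockdown activity. The defaults give a 16-fold separation
#' between the two peaks with clearly resolved modes, a 15% non-responder
#' fraction, 100 sorted cells per library element per fraction and 2e6 reads
#' per fraction.
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene sgRNAs per gene (default 5).
#' @param n_ntc Non-targeting control sgRNAs (default 250).
#' @param coverage Cells per library element and sorted fraction (default
#'   100); the simulated pool holds `3 * coverage * library size` cells.
#' @param depth Sequencing reads per sorted fraction (default 2e6).
#' @param mu_induced Mean log10 fluorescence of responding cells (default 4).
#' @param mu_off Mean log10 fluorescence of non-responders (default 2.8).
#' @param sigma Within-peak log10 standard deviation (default 0.25).
#' @param pi_off Baseline non-responder fraction (default 0.15; must be
#'   below 0.5 so the responding peak stays the major mode).
#' @param fallback_quantile Gate quantile used when no valley can be found
#'   (default 0.15).
#' @param spacer_length Length of the random spacers (default 20).
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes, sgrnas_per_gene = 5L, n_ntc = 250L,
                              coverage = 100L, depth = 2e6,
                              mu_induced = 4.0, mu_off = 2.8, sigma = 0.25,
                              pi_off = 0.15, fallback_quantile = 0.15,
                              spacer_length = 20L) {
  if (n_genes <= 0 || sgrnas_per_gene <= 0 || coverage <= 0 || depth <= 0) {
    stop_sortscreen("all size parameters must be positive",
                    class = "sortscreen_config_error")
  }
  if (n_ntc < 0) {
    stop_sortscreen("n_ntc must be non-negative",
                    class = "sortscreen_config_error")
  }
  if (mu_off >= mu_induced) {
    stop_sortscreen("mu_off must lie below mu_induced",
                    class = "sortscreen_config_error")
  }
  if (pi_off < 0 || pi_off >= 0.5 || sigma <= 0) {
    stop_sortscreen("need 0 <= pi_off < 0.5 and sigma > 0",
                    class = "sortscreen_config_error")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      sgrnas_per_gene = as.integer(sgrnas_per_gene),
      n_ntc = as.integer(n_ntc),
      coverage = as.integer(coverage),
      depth = depth,
      mu_induced = mu_induced, mu_off = mu_off, sigma = sigma,
      pi_off = pi_off, fallback_quantile = fallback_quantile,
      spacer_length = as.integer(spacer_length)
    ),
    class = "screen_sim_config"
  )
}

#' Build a synthetic sgRNA library
#'
#' Generates `n_genes * sgrnas_per_gene` gene-targeting entries (one
#' transcription start site per gene) plus `n_ntc` non-targeting controls,
#' with distinct random spacers of fixed length.
#'
#' @inheritParams screen_sim_config
#' @param seed RNG seed; the same seed reproduces the library exactly.
#' @param library_id Library label (default `"SIM1"`).
#' @return A library tibble (see [read_library_table()] for the columns).
#' @export
#' @examples
#' build_library(n_genes = 3, sgrnas_per_gene = 2, n_ntc = 4, seed = 7)
build_library <- function(n_genes, sgrnas_per_gene = 5L, n_ntc = 250L,
                          seed = NULL, spacer_length = 20L,
                          library_id = "SIM1") {
  if (n_genes < 1 || sgrnas_per_gene < 1 || n_ntc < 0) {
    stop_sortscreen("library sizes must be positive",
                    class = "sortscreen_config_error")
  }
  n_total <- n_genes * sgrnas_per_gene + n_ntc
  if (log(n_total) > spacer_length * log(4)) {
    stop_sortscreen("requested library exceeds the distinct-spacer space",
                    class = "sortscreen_config_error")
  }
  gene <- sprintf("gene_%0*d", nchar(n_genes), seq_len(n_genes))
  targets <- rep(gene, each = sgrnas_per_gene)
  with_seed_(seed, {
    spacers <- random_spacers(n_total, spacer_length)
    tibble(
      sgrna_id = c(
        paste0(targets, "_sg", rep(seq_len(sgrnas_per_gene), n_genes)),
        sprintf("ntc_%04d", seq_len(n_ntc))
      ),
      target = c(targets, rep("NTC", n_ntc)),
      tss_id = c(paste0(targets, "_TSS1"), rep(NA_character_, n_ntc)),
      spacer = spacers,
      library_id = library_id
    )
  })
}

random_spacers <- function(n, len) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * len, replace = TRUE),
                nrow = k)
    apply(m, 1, paste0, collapse = "")
  }
  spacers <- unique(draw(n))
  while (length(spacers) < n) {
    spacers <- unique(c(spacers, draw(n - length(spacers))))
  }
  spacers[seq_len(n)]
}

#' Assign ground-truth gene effects and sgRNA activities
#'
#' Designates random subsets of the library's genes as positive and negative
#' regulators and draws their effect sizes and per-sgRNA knockdown
#' activities. The effect size `beta` is the log10 shift of a responding
#' cell's reporter fluorescence when the gene is fully silenced; a positive
#' regulator of the pathway gets `beta < 0` (silencing lowers the reporter)
#' and a negative regulator `beta > 0`. All other genes get `beta = 0`;
#' non-targeting controls contribute no shift.
#'
#' @param library Library tibble.
#' @param fraction_positive,fraction_negative Fractions of genes designated
#'   positive/negative regulators (their sum must not exceed 1). Counts are
#'   `round(fraction * n_genes)`.
#' @param beta_magnitude Either a positive number (point-mass magnitude) or a
#'   function `n -> n` positive magnitudes. Default `runif(n, 0.6, 1.2)`
#'   log10 units — strong regulators comparable to a near-complete block of
#'   induction.
#' @param activity Function `n -> n` knockdown activities in `[0, 1]` per
#'   sgRNA. Default `rbeta(n, 5, 1)` (most sgRNAs active, a tail of weak
#'   ones).
#' @param seed RNG seed.
#' @return A list of class `gene_effect_map` with tibbles `gene_effects`
#'   (`gene`, `beta`) and `sgrna_activity` (`sgrna_id`, `activity`).
#' @export
assign_gene_effects <- function(library, fraction_positive = 0,
                                fraction_negative = 0,
                                beta_magnitude = function(n) runif(n, 0.6, 1.2),
                                activity = function(n) rbeta(n, 5, 1),
                                seed = NULL) {
  if (fraction_positive < 0 || fraction_negative < 0 ||
      fraction_positive + fraction_negative > 1) {
    stop_sortscreen("regulator fractions must be >= 0 and sum to <= 1",
                    class = "sortscreen_config_error")
  }
  if (is.numeric(beta_magnitude)) {
    mag <- force(beta_magnitude)
    beta_magnitude <- function(n) rep(mag, length.out = n)
  }
  genes <- unique(library$target[!is_ntc(library)])
  n_pos <- round(fraction_positive * length(genes))
  n_neg <- round(fraction_negative * length(genes))
  targeting <- library$sgrna_id[!is_ntc(library)]
  with_seed_(seed, {
    chosen <- sample(genes, n_pos + n_neg)
    beta <- setNames(numeric(length(genes)), genes)
    if (n_pos > 0) beta[chosen[seq_len(n_pos)]] <- -abs(beta_magnitude(n_pos))
    if (n_neg > 0) beta[chosen[n_pos + seq_len(n_neg)]] <-
        abs(beta_magnitude(n_neg))
    structure(
      list(
        gene_effects = tibble(gene = genes, beta = unname(beta[genes])),
        sgrna_activity = tibble(
          sgrna_id = targeting,
          activity = pmin(pmax(activity(length(targeting)), 0), 1)
        )
      ),
      class = "gene_effect_map"
    )
  })
}

#' Simulate an infected, induced cell population
#'
#' Draws `3 * coverage * library size` cells, each carrying exactly one
#' sgRNA chosen uniformly (multiplicity of infection below one, no
#' bottlenecking). A cell is a non-responder with probability `pi_off`, in
#' which case its log10 fluorescence is `mu_off + sigma * z`; otherwise it is
#' `mu_induced + activity * beta + sigma * z` with `z` standard normal and
#' `beta` the effect of the cell's sgRNA target (0 for non-targeting
#' controls and unperturbed genes).
#'
#' @param library Library tibble.
#' @param effects A `gene_effect_map` from [assign_gene_effects()].
#' @param config A `screen_sim_config`.
#' @param seed RNG seed.
#' @return A tibble with one row per cell: `sgrna_id`, `fluorescence`
#'   (linear scale, positive).
#' @export
simulate_cells <- function(library, effects, config, seed = NULL) {
  stopifnot(inherits(config, "screen_sim_config"))
  n_sgrna <- nrow(library)
  n_cells <- 3L * config$coverage * n_sgrna
  beta_by_gene <- setNames(effects$gene_effects$beta, effects$gene_effects$gene)
  act <- setNames(effects$sgrna_activity$activity,
                  effects$sgrna_activity$sgrna_id)
  shift <- numeric(n_sgrna)
  targeting <- !is_ntc(library)
  shift[targeting] <- act[library$sgrna_id[targeting]] *
    beta_by_gene[library$target[targeting]]
  if (anyNA(shift)) {
    stop_sortscreen("effects do not cover every library gene/sgRNA",
                    class = "sortscreen_config_error")
  }
  with_seed_(seed, {
    idx <- sample.int(n_sgrna, n_cells, replace = TRUE)
    off <- runif(n_cells) < config$pi_off
    mu <- ifelse(off, config$mu_off, config$mu_induced + shift[idx])
    logf <- mu + config$sigma * rnorm(n_cells)
    tibble(sgrna_id = library$sgrna_id[idx], fluorescence = 10^logf)
  })
}

#' Sort cells into low, medium and high fractions
#'
#' Reproduces the gating of a bimodal induced-reporter histogram: the "low"
#' gate is placed at the valley of a smoothed log10-fluorescence histogram
#' between its two largest modes (kernel density on a 256-point grid,
#' Silverman bandwidth), and the remaining cells — the right-shifted
#' responding peak — are split at their median into equally sized "medium"
#' (lower half) and "high" (upper half) fractions. If the smoothed histogram
#' has fewer than two modes, the gate falls back to a fixed quantile of the
#' distribution and a warning is issued.
#'
#' @param population Cell tibble from [simulate_cells()] (needs >= 10 cells).
#' @param fallback_quantile Quantile gate used when no valley exists.
#' @return A list of class `sorted_fractions`: `fraction` (factor
#'   low/medium/high per cell, partitioning the population exactly, with
#'   medium and high sizes differing by at most one) and `valley` (gate
#'   boundary, log10 units).
#' @export
gate_cells <- function(population, fallback_quantile = 0.15) {
  x <- log10(population$fluorescence)
  if (length(x) < 10) {
    stop_sortscreen("gating needs at least 10 cells",
                    class = "sortscreen_config_error")
  }
  valley <- find_valley(x)
  if (is.na(valley)) {
    rlang::warn("no valley between two modes; using fallback quantile gate",
                class = "sortscreen_gate_fallback")
    valley <- unname(quantile(x, fallback_quantile, type = 7))
  }
  low <- x < valley
  fraction <- character(length(x))
  fraction[low] <- "low"
  rest <- which(!low)
  # ties.method = "first" keeps the partition exact even with tied values
  r <- rank(x[rest], ties.method = "first")
  n_med <- ceiling(length(rest) / 2)
  fraction[rest[r <= n_med]] <- "medium"
  fraction[rest[r > n_med]] <- "high"
  structure(
    list(
      fraction = factor(fraction, levels = c("low", "medium", "high")),
      valley = valley
    ),
    class = "sorted_fractions"
  )
}

# valley (grid x at the density minimum) between the two highest modes of a
# 256-point kernel density estimate; NA when fewer than two modes exist
find_valley <- function(x) {
  if (length(unique(x)) < 2) return(NA_real_)
  d <- density(x, n = 256)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(NA_real_)
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Sequence sorted fractions into a count matrix
#'
#' Models pooled amplicon sequencing: for each sorted fraction the read
#' counts are one multinomial draw of size `depth` with probabilities
#' proportional to the fraction's per-sgRNA cell tallies, so every column
#' sums to `depth` exactly. An empty fraction yields an all-zero column and
#' a warning.
#'
#' @param fractions A `sorted_fractions` object from [gate_cells()].
#' @param population The cell tibble that was gated.
#' @param library Library tibble (fixes the full sgRNA row set).
#' @param depth Reads per fraction.
#' @param seed RNG seed.
#' @return Count tibble: `sgrna_id`, `low`, `medium`, `high`.
#' @export
sequence_fractions <- function(fractions, population, library, depth,
                               seed = NULL) {
  stopifnot(inherits(fractions, "sorted_fractions"))
  if (depth <= 0) {
    stop_sortscreen("depth must be positive",
                    class = "sortscreen_config_error")
  }
  sg <- factor(population$sgrna_id, levels = library$sgrna_id)
  out <- tibble(sgrna_id = library$sgrna_id)
  with_seed_(seed, {
    for (frac in c("low", "medium", "high")) {
      tally <- tabulate(sg[fractions$fraction == frac],
                        nbins = nrow(library))
      if (sum(tally) == 0) {
        rlang::warn(paste0("fraction '", frac, "' holds no cells"),
                    class = "sortscreen_empty_fraction")
        out[[frac]] <- 0L
      } else {
        out[[frac]] <- as.integer(rmultinom(1, size = depth, prob = tally))
      }
    }
  })
  out
}

#' Simulate a complete three-fraction sorting screen
#'
#' Composes [build_library()], [assign_gene_effects()], [simulate_cells()],
#' [gate_cells()] and [sequence_fractions()] under a single seed that is
#' split deterministically across the stages, and returns the count matrix
#' together with the ground truth needed for recovery tests.
#'
#' @param config A `screen_sim_config`.
#' @param seed Single RNG seed for the whole screen.
#' @param library Optional pre-built library (default: built from `config`).
#' @param effects Optional pre-built `gene_effect_map`; when `NULL` one is
#'   drawn using `fraction_positive`/`fraction_negative` and the magnitude /
#'   activity distributions of [assign_gene_effects()].
#' @param fraction_positive,fraction_negative,beta_magnitude,activity Passed
#'   to [assign_gene_effects()] when `effects` is `NULL`.
#' @return A list of class `screen_sim`: `counts`, `library`, `effects`,
#'   `valley`, and `fraction_sizes` (cells per gate).
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 20, n_ntc = 20,
#'                                          coverage = 20, depth = 1e4),
#'                        seed = 1)
#' sim$counts
simulate_screen <- function(config, seed = 1L, library = NULL, effects = NULL,
                            fraction_positive = 0, fraction_negative = 0,
                            beta_magnitude = function(n) runif(n, 0.6, 1.2),
                            activity = function(n) rbeta(n, 5, 1)) {
  stopifnot(inherits(config, "screen_sim_config"))
  seeds <- split_seed(seed, c("library", "effects", "cells", "reads"))
  if (is.null(library)) {
    library <- build_library(config$n_genes, config$sgrnas_per_gene,
                             config$n_ntc, seed = seeds[["library"]],
                             spacer_length = config$spacer_length)
  }
  if (is.null(effects)) {
    effects <- assign_gene_effects(library, fraction_positive,
                                   fraction_negative, beta_magnitude,
                                   activity, seed = seeds[["effects"]])
  }
  cells <- simulate_cells(library, effects, config, seed = seeds[["cells"]])
  fractions <- gate_cells(cells, config$fallback_quantile)
  counts <- sequence_fractions(fractions, cells, library, config$depth,
                               seed = seeds[["reads"]])
  structure(
    list(
      counts = counts, library = library, effects = effects,
      valley = fractions$valley,
      fraction_sizes = table(fractions$fraction)
    ),
    class = "screen_sim"
  )
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated sorted screen:", nrow(x$library), "sgRNAs (",
      sum(is_ntc(x$library)), "NTCs ),",
      sum(x$fraction_sizes), "cells\n")
  cat("  gate valley (log10):", format(x$valley, digits = 4),
      "| fraction sizes:",
      paste(names(x$fraction_sizes), as.integer(x$fraction_sizes),
            collapse = ", "), "\n")
  invisible(x)
}
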