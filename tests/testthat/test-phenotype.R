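test_that("frequency normalization matches the pseudocount formula and sums to one", {
  lib <- tiny_library(n_genes = 1, n_ntc = 1)  # 3 sgRNAs
  counts <- tibble::tibble(sgrna_id = lib$sgrna_id, low = c(8L, 2L, 0L),
                           high = c(4L, 4L, 4L))
  freqs <- normalize_counts(counts, lib, pseudocount = 1)
  expect_equal(freqs$low, c(9, 3, 1) / 13)
  expect_equal(freqs$high, rep(1 / 3, 3))

  withr::with_seed(2, {
    lib2 <- tiny_library(n_genes = 5, n_ntc = 5)
    counts2 <- tiny_counts(lib2, seed = 2)
    f2 <- normalize_counts(counts2, lib2, pseudocount = 0.5)
    expect_equal(colSums(f2[c("low", "medium", "high")]),
                 c(low = 1, medium = 1, high = 1))
  })
  expect_error(normalize_counts(counts, lib, pseudocount = 0),
               class = "sortscreen_config_error")
})

test_that("frequencies are normalized within each library separately", {
  libA <- tiny_library(n_genes = 2, n_ntc = 2)
  libB <- build_library(2, 2, 2, seed = 77, spacer_length = 8,
                        library_id = "L2")
  libB$sgrna_id <- paste0("B_", libB$sgrna_id)
  lib <- dplyr::bind_rows(libA, libB)
  counts <- tiny_counts(lib, seed = 3)
  freqs <- normalize_counts(counts, lib, pseudocount = 1)
  sums <- tapply(freqs$low, freqs$library_id, sum)
  expect_equal(as.vector(sums), c(1, 1))
})

test_that("log2 fold changes obey the hand-computed example, path identity and antisymmetry", {
  lib <- tiny_library(n_genes = 1, n_ntc = 0)  # 2 sgRNAs
  counts <- tibble::tibble(sgrna_id = lib$sgrna_id,
                           low = c(30L, 10L), high = c(10L, 30L))
  freqs <- normalize_counts(counts, lib, pseudocount = 1)
  lfc <- sgrna_log2fc(freqs, "low", "high")
  expect_equal(lfc$lfc[1], log2(31 / 11))
  expect_equal(lfc$lfc[2], log2(11 / 31))

  # identical columns give all-zero fold changes
  same <- tibble::tibble(sgrna_id = lib$sgrna_id, low = c(5L, 9L),
                         high = c(5L, 9L))
  expect_equal(sgrna_log2fc(normalize_counts(same, lib), "low", "high")$lfc,
               c(0, 0))

  expect_error(sgrna_log2fc(freqs, "low", "nope"),
               class = "sortscreen_config_error")
  expect_error(sgrna_log2fc(freqs, "low", "low"),
               class = "sortscreen_config_error")

  # properties on random count matrices
  lib3 <- tiny_library(n_genes = 6, n_ntc = 4)
  withr::with_seed(11, {
    for (i in 1:25) {
      cts <- tiny_counts(lib3, seed = sample.int(1e6, 1))
      f <- normalize_counts(cts, lib3, pseudocount = 1)
      ab <- sgrna_log2fc(f, "low", "medium")$lfc
      bc <- sgrna_log2fc(f, "medium", "high")$lfc
      ac <- sgrna_log2fc(f, "low", "high")$lfc
      expect_equal(ac, ab + bc, tolerance = 1e-12)
      expect_equal(sgrna_log2fc(f, "high", "low")$lfc, -ac,
                   tolerance = 1e-12)
    }
  })
})

test_that("NTC centering zeroes the control median and is idempotent", {
  lib <- tiny_library(n_genes = 3, n_ntc = 5)
  counts <- tiny_counts(lib, seed = 4)
  phen <- sgrna_log2fc(normalize_counts(counts, lib), "low", "high")
  centered <- center_to_ntc(phen, lib)
  ntc_ids <- lib$sgrna_id[lib$target == "NTC"]
  ntc_med <- median(phen$lfc[phen$sgrna_id %in% ntc_ids])
  expect_equal(centered$lfc, phen$lfc - ntc_med)
  expect_equal(median(centered$lfc[centered$sgrna_id %in% ntc_ids]), 0)
  expect_equal(center_to_ntc(centered, lib), centered)

  no_ntc <- tiny_library(n_genes = 3, n_ntc = 0)
  phen2 <- sgrna_log2fc(normalize_counts(tiny_counts(no_ntc), no_ntc),
                        "low", "high")
  expect_error(center_to_ntc(phen2, no_ntc),
               class = "sortscreen_config_error")
})

test_that("epsilon averages the extreme sgRNAs with deterministic tie-breaking", {
  expect_equal(gene_epsilon(rep(1.3, 5)), 1.3)
  expect_equal(gene_epsilon(rep(0, 5)), 0)
  expect_equal(gene_epsilon(c(-3.0, -2.5, 0.1, -0.2, 0.05)),
               mean(c(-3.0, -2.5, -0.2)))
  # fewer sgRNAs than k: average all of them
  expect_equal(gene_epsilon(c(2, -4)), -1)
  # ties in |lfc| resolved by ascending id
  expect_equal(gene_epsilon(c(1, -1, 1, -1), k = 3, ids = c("d", "c", "b", "a")),
               mean(c(-1, 1, -1)))
  expect_error(gene_epsilon(numeric(0)), class = "sortscreen_config_error")
  expect_error(gene_epsilon(1, k = 0), class = "sortscreen_config_error")
})

test_that("epsilon agrees with both independent oracles on random vectors", {
  withr::with_seed(13, {
    for (i in 1:200) {
      v <- rnorm(5)
      expect_equal(gene_epsilon(v), oracle_epsilon_selection(v))
      expect_equal(gene_epsilon(v), oracle_epsilon_subsets(v))
      expect_lte(abs(gene_epsilon(v)), max(abs(v)))
    }
    # with repeated absolute values the selection oracle fixes the answer
    v <- c(0.5, -0.5, 0.5, 0.2, -0.5)
    expect_equal(gene_epsilon(v), oracle_epsilon_selection(v))
  })
})

test_that("Mann-Whitney p matches wilcox.test and enumeration on small samples", {
  withr::with_seed(17, {
    for (i in 1:30) {
      x <- rnorm(5)
      y <- rnorm(sample(6:12, 1))
      p_pkg <- gene_pvalue(x, y)
      expect_equal(p_pkg,
                   suppressWarnings(stats::wilcox.test(x, y,
                                                       exact = TRUE))$p.value,
                   tolerance = 1e-12)
      expect_equal(p_pkg, oracle_mw_enum(x, y), tolerance = 1e-12)
      # swapping the samples leaves the two-sided p unchanged
      expect_equal(gene_pvalue(y, x), p_pkg, tolerance = 1e-12)
    }
  })
})

test_that("tied or large samples use the tie-corrected normal approximation", {
  withr::with_seed(19, {
    # ties force the approximate path
    x <- c(1, 2, 2, 3, 5)
    y <- c(2, 3, 3, 4, 4, 6, 7, 1)
    expect_equal(gene_pvalue(x, y),
                 suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                     correct = FALSE))$p.value,
                 tolerance = 1e-12)
    # min(n, m) > 8 likewise
    x2 <- rnorm(9)
    y2 <- rnorm(20)
    expect_equal(gene_pvalue(x2, y2),
                 stats::wilcox.test(x2, y2, exact = FALSE,
                                    correct = FALSE)$p.value,
                 tolerance = 1e-12)
  })
  # a gene equal (as a multiset) to a symmetric reference: no separation
  ref <- c(-2, -1, 0, 1, 2)
  expect_gte(gene_pvalue(ref, ref), 0.5)
  # degenerate all-identical values
  expect_equal(gene_pvalue(rep(1, 5), rep(1, 10)), 1)
  expect_error(gene_pvalue(numeric(0), 1), class = "sortscreen_config_error")
})

test_that("gene scoring composes epsilon, p and hit strength per target", {
  sim <- tiny_screen(seed = 41)
  scores <- score_genes(sim$counts, sim$library, "low", "high")
  genes <- unique(sim$library$target[sim$library$target != "NTC"])
  expect_setequal(scores$target, genes)
  expect_false(any(scores$target == "NTC"))
  expect_true(all(scores$p_value > 0 & scores$p_value <= 1))
  expect_equal(scores$hit_strength, scores$epsilon * -log10(scores$p_value))
  expect_equal(scores$n_sgrnas, rep(5L, length(genes)))

  # reversing the comparison flips epsilon and hit strength, p unchanged
  rev_scores <- score_genes(sim$counts, sim$library, "high", "low")
  expect_equal(rev_scores$epsilon, -scores$epsilon)
  expect_equal(rev_scores$hit_strength, -scores$hit_strength)
  expect_equal(rev_scores$p_value, scores$p_value)

  # epsilon bounded by the gene's largest absolute centered fold change
  phen <- center_to_ntc(
    sgrna_log2fc(normalize_counts(sim$counts, sim$library), "low", "high"),
    sim$library
  )
  lfc <- stats::setNames(phen$lfc, phen$sgrna_id)
  for (g in utils::head(genes, 5)) {
    ids <- sim$library$sgrna_id[sim$library$target == g]
    expect_lte(abs(scores$epsilon[scores$target == g]), max(abs(lfc[ids])))
  }
})

test_that("a p-value of one yields zero hit strength", {
  lib <- tiny_library(n_genes = 1, n_ntc = 10)
  # gene counts identical to every NTC: no separation whatsoever
  counts <- tibble::tibble(sgrna_id = lib$sgrna_id,
                           low = rep(20L, 12), high = rep(20L, 12))
  scores <- score_genes(counts, lib, "low", "high")
  expect_equal(scores$p_value, 1)
  expect_equal(scores$hit_strength, 0)
})
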