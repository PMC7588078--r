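test_that("build_library produces the requested structure deterministically", {
  lib <- build_library(20, 5, 10, seed = 3, spacer_length = 10)
  expect_equal(nrow(lib), 20 * 5 + 10)
  expect_equal(sum(lib$target == "NTC"), 10)
  expect_equal(anyDuplicated(lib$spacer), 0L)
  expect_true(all(nchar(lib$spacer) == 10))
  expect_equal(dplyr::n_distinct(lib$target[lib$target != "NTC"]), 20)

  expect_identical(lib, build_library(20, 5, 10, seed = 3, spacer_length = 10))

  single <- build_library(1, 1, 0, seed = 1)
  expect_equal(nrow(single), 1)
  expect_false(any(single$target == "NTC"))

  # 4^2 = 16 distinct spacers cannot cover 20 requests
  expect_error(build_library(10, 2, 0, seed = 1, spacer_length = 2),
               class = "sortscreen_config_error")
})

test_that("gene effects follow the requested fractions and sign convention", {
  lib <- build_library(1000, 2, 10, seed = 5, spacer_length = 12)
  null_eff <- assign_gene_effects(lib, 0, 0, seed = 1)
  expect_true(all(null_eff$gene_effects$beta == 0))
  expect_true(all(null_eff$sgrna_activity$activity >= 0 &
                    null_eff$sgrna_activity$activity <= 1))
  expect_equal(nrow(null_eff$sgrna_activity), 2000)

  # every gene a positive regulator with point-mass magnitude m => beta = -m
  all_pos <- assign_gene_effects(lib, 1, 0, beta_magnitude = 0.7, seed = 1)
  expect_true(all(all_pos$gene_effects$beta == -0.7))

  # fraction 0.02 of 1000 genes => exactly 20 genes with beta < 0
  some <- assign_gene_effects(lib, 0.02, 0.01, seed = 9)
  expect_equal(sum(some$gene_effects$beta < 0), 20)
  expect_equal(sum(some$gene_effects$beta > 0), 10)
  expect_true(all(abs(some$gene_effects$beta[some$gene_effects$beta != 0])
                  >= 0.6))

  expect_error(assign_gene_effects(lib, 0.7, 0.4),
               class = "sortscreen_config_error")
})

test_that("cell fluorescence follows the two-component lognormal model", {
  lib <- build_library(10, 2, 5, seed = 2, spacer_length = 10)
  cfg <- screen_sim_config(10, 2, 5, coverage = 200, depth = 1e4,
                           pi_off = 0, sigma = 0.2)
  eff <- assign_gene_effects(lib, 0, 0, seed = 1)
  cells <- simulate_cells(lib, eff, cfg, seed = 11)
  n <- nrow(cells)
  expect_equal(n, 3 * 200 * nrow(lib))
  # all-null, pi_off 0: mean log10 fluorescence within 3 SE of mu_induced
  expect_lt(abs(mean(log10(cells$fluorescence)) - cfg$mu_induced),
            3 * cfg$sigma / sqrt(n))

  # full block of one gene drags its cells to the off peak
  eff2 <- eff
  eff2$gene_effects$beta[1] <- cfg$mu_off - cfg$mu_induced
  g1 <- eff2$gene_effects$gene[1]
  ids1 <- lib$sgrna_id[lib$target == g1]
  eff2$sgrna_activity$activity[eff2$sgrna_activity$sgrna_id %in% ids1] <- 1
  cells2 <- simulate_cells(lib, eff2, cfg, seed = 12)
  blocked <- log10(cells2$fluorescence[cells2$sgrna_id %in% ids1])
  expect_lt(abs(mean(blocked) - cfg$mu_off),
            4 * cfg$sigma / sqrt(length(blocked)))
})

test_that("valley gating recovers a known mixture weight and splits the rest evenly", {
  withr::with_seed(21, {
    n <- 20000
    low_frac <- 0.10
    x <- c(10^rnorm(n * low_frac, 2.5, 0.15),
           10^rnorm(n * (1 - low_frac), 4.0, 0.15))
    pop <- tibble::tibble(sgrna_id = "s", fluorescence = x)
  })
  fr <- gate_cells(pop)
  sizes <- table(fr$fraction)
  expect_equal(sum(sizes), n)
  expect_lt(abs(sizes[["low"]] / n - low_frac), 0.01)
  expect_lte(abs(sizes[["medium"]] - sizes[["high"]]), 1)
  expect_gt(fr$valley, 2.5)
  expect_lt(fr$valley, 4.0)
})

test_that("unimodal input falls back to the quantile gate with an exact partition", {
  pop <- tibble::tibble(sgrna_id = "s", fluorescence = rep(100, 11))
  expect_warning(fr <- gate_cells(pop), class = "sortscreen_gate_fallback")
  sizes <- table(fr$fraction)
  expect_equal(sum(sizes), 11)
  expect_equal(sizes[["low"]], 0L)  # nothing strictly below the gate value
  expect_lte(abs(sizes[["medium"]] - sizes[["high"]]), 1)

  expect_error(gate_cells(pop[1:5, ]), class = "sortscreen_config_error")
})

test_that("gating is equivariant under multiplicative rescaling of fluorescence", {
  withr::with_seed(5, {
    x <- c(10^rnorm(3000, 2.6, 0.2), 10^rnorm(7000, 4, 0.2))
  })
  pop <- tibble::tibble(sgrna_id = "s", fluorescence = x)
  f1 <- gate_cells(pop)
  f2 <- gate_cells(dplyr::mutate(pop, fluorescence = fluorescence * 37.5))
  expect_equal(f1$fraction, f2$fraction)
  expect_equal(f2$valley - f1$valley, log10(37.5), tolerance = 1e-8)
})

test_that("sequencing draws multinomial counts conserving depth", {
  lib <- tiny_library(n_genes = 4, n_ntc = 2)
  cfg <- screen_sim_config(4, 2, 2, coverage = 50, depth = 5000)
  eff <- assign_gene_effects(lib, 0, 0, seed = 1)
  cells <- simulate_cells(lib, eff, cfg, seed = 3)
  fr <- gate_cells(cells)
  counts <- sequence_fractions(fr, cells, lib, depth = 5000, seed = 4)
  expect_equal(colSums(counts[c("low", "medium", "high")]),
               c(low = 5000, medium = 5000, high = 5000))

  # single-sgRNA fraction receives the whole depth
  one <- tibble::tibble(sgrna_id = rep(lib$sgrna_id[1], 20),
                        fluorescence = 10^rnorm(20, 4, 0.1))
  fr1 <- structure(list(
    fraction = factor(rep("high", 20), levels = c("low", "medium", "high")),
    valley = 3
  ), class = "sorted_fractions")
  # both low and medium are empty here: one warning per empty fraction
  warns <- testthat::capture_warnings(
    counts1 <- sequence_fractions(fr1, one, lib, depth = 100, seed = 1)
  )
  expect_length(warns, 2)
  expect_match(warns, "holds no cells", all = TRUE)
  expect_equal(counts1$high[1], 100L)
  expect_equal(sum(counts1$low), 0L)

  # expected counts: depth * cell share, observed within 4 SD (binomial)
  tally <- tabulate(factor(cells$sgrna_id, levels = lib$sgrna_id)[
    fr$fraction == "high"], nbins = nrow(lib))
  p <- tally / sum(tally)
  expected <- 5000 * p
  sd4 <- 4 * sqrt(5000 * p * (1 - p))
  expect_true(all(abs(counts$high - expected) <= pmax(sd4, 1)))
})

test_that("a full simulated screen is deterministic and partitions its cells", {
  sim1 <- tiny_screen(seed = 8)
  sim2 <- tiny_screen(seed = 8)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$library, sim2$library)
  expect_equal(sum(sim1$fraction_sizes),
               3 * 25 * nrow(sim1$library))
  expect_lte(abs(sim1$fraction_sizes[["medium"]] -
                   sim1$fraction_sizes[["high"]]), 1)
  expect_false(identical(sim1$counts, tiny_screen(seed = 9)$counts))
})

test_that("a full-block regulator enriches its sgRNAs in the low fraction", {
  cfg <- screen_sim_config(n_genes = 20, n_ntc = 25, coverage = 25,
                           depth = 5e4)
  lib <- build_library(20, 5, 25, seed = 30)
  eff <- assign_gene_effects(lib, 0, 0, seed = 30)
  eff$gene_effects$beta[1] <- cfg$mu_off - cfg$mu_induced
  g <- eff$gene_effects$gene[1]
  ids <- lib$sgrna_id[lib$target == g]
  eff$sgrna_activity$activity[eff$sgrna_activity$sgrna_id %in% ids] <- 1
  sim <- simulate_screen(cfg, seed = 31, library = lib, effects = eff)
  in_g <- sim$counts$sgrna_id %in% ids
  freq_low <- sum(sim$counts$low[in_g]) / sum(sim$counts$low)
  freq_high <- sum(sim$counts$high[in_g]) / sum(sim$counts$high)
  expect_gt(freq_low, freq_high)
})

test_that("stronger effects do not weaken the expected pooled low-vs-high log-ratio", {
  betas <- c(-0.3, -0.6, -1.2)
  ratios <- vapply(betas, function(b) {
    vals <- vapply(1:3, function(s) {
      cfg <- screen_sim_config(n_genes = 10, n_ntc = 15, coverage = 25,
                               depth = 3e4)
      lib <- build_library(10, 5, 15, seed = 100 + s)
      eff <- assign_gene_effects(lib, 0, 0, seed = 100 + s)
      eff$gene_effects$beta[1] <- b
      ids <- lib$sgrna_id[lib$target == eff$gene_effects$gene[1]]
      eff$sgrna_activity$activity[eff$sgrna_activity$sgrna_id %in% ids] <- 0.95
      sim <- simulate_screen(cfg, seed = 200 + s, library = lib,
                             effects = eff)
      in_g <- sim$counts$sgrna_id %in% ids
      abs(log2((sum(sim$counts$low[in_g]) + 1) / (sum(sim$counts$low) + 1)) -
            log2((sum(sim$counts$high[in_g]) + 1) / (sum(sim$counts$high) + 1)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})
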