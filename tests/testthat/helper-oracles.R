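# Independent oracles used to freeze expected values. These deliberately use
# different algorithms from the package implementation.

# epsilon by repeated selection: scan the remaining sgRNAs for the largest
# absolute value (ties: smallest id), remove it, k times, then average
oracle_epsilon_selection <- function(lfc, k = 3, ids = seq_along(lfc)) {
  kk <- min(k, length(lfc))
  picked <- numeric(kk)
  remaining <- seq_along(lfc)
  for (j in seq_len(kk)) {
    best <- remaining[1]
    for (i in remaining) {
      if (abs(lfc[i]) > abs(lfc[best]) ||
          (abs(lfc[i]) == abs(lfc[best]) && ids[i] < ids[best])) {
        best <- i
      }
    }
    picked[j] <- lfc[best]
    remaining <- setdiff(remaining, best)
  }
  mean(picked)
}

# epsilon by exhaustive subset enumeration: among all size-k subsets, take
# the one with the largest sum of absolute values (unique for no-tie input)
oracle_epsilon_subsets <- function(lfc, k = 3) {
  kk <- min(k, length(lfc))
  subs <- utils::combn(seq_along(lfc), kk)
  sums <- apply(subs, 2, function(ix) sum(abs(lfc[ix])))
  mean(lfc[subs[, which.max(sums)]])
}

# exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# assignments of the pooled ranks to the first sample
oracle_mw_enum <- function(x, y) {
  n <- length(x)
  m <- length(y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled_ranks <- utils::combn(n + m, n)
  u_null <- colSums(pooled_ranks) - n * (n + 1) / 2
  p_low <- mean(u_null <= u_obs)
  p_high <- mean(u_null >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# null distribution of U for sample sizes (n, m) by full enumeration,
# returned as a function u -> c(P(U <= u), P(U >= u))
oracle_mw_tails <- function(n, m) {
  u_null <- colSums(utils::combn(n + m, n)) - n * (n + 1) / 2
  function(u) c(low = mean(u_null <= u), high = mean(u_null >= u))
}

# brute-force read assignment: Hamming distance of the cropped window to
# every spacer, assignment per the minimal-distance/ambiguity rule
oracle_count_reads <- function(reads, spacers, crop_offset, max_mismatch) {
  L <- nchar(spacers[1])
  counts <- integer(length(spacers))
  unassigned <- 0L
  ambiguous <- 0L
  for (r in reads) {
    if (nchar(r) < crop_offset + L) {
      unassigned <- unassigned + 1L
      next
    }
    w <- substr(r, crop_offset + 1, crop_offset + L)
    d <- vapply(spacers, function(s) {
      sum(strsplit(w, "")[[1]] != strsplit(s, "")[[1]])
    }, numeric(1))
    dmin <- min(d)
    if (dmin > max_mismatch) {
      unassigned <- unassigned + 1L
    } else if (sum(d == dmin) > 1L) {
      ambiguous <- ambiguous + 1L
    } else {
      counts[which.min(d)] <- counts[which.min(d)] + 1L
    }
  }
  list(counts = counts, unassigned = unassigned, ambiguous = ambiguous)
}

# hypergeometric upper tail by enumeration over placements of set B
oracle_overlap_tail <- function(n_a, n_b, k, universe) {
  placements <- utils::combn(universe, n_b)
  mean(apply(placements, 2, function(b) sum(b <= n_a) >= k))
}

# small library fixture: n_genes genes x 2 sgRNAs + n_ntc NTCs with short
# deterministic spacers
tiny_library <- function(n_genes = 3, n_ntc = 4, sgrnas_per_gene = 2) {
  build_library(n_genes, sgrnas_per_gene, n_ntc, seed = 42,
                spacer_length = 8, library_id = "L1")
}

# deterministic small count table over a library
tiny_counts <- function(library, seed = 1, samples = c("low", "medium", "high")) {
  withr::with_seed(seed, {
    out <- tibble::tibble(sgrna_id = library$sgrna_id)
    for (s in samples) {
      out[[s]] <- as.integer(rpois(nrow(library), 50))
    }
    out
  })
}

# small simulated screen shared across tests
tiny_screen <- function(seed = 1, n_genes = 20, n_ntc = 25, coverage = 25,
                        depth = 5e4, ...) {
  simulate_screen(
    screen_sim_config(n_genes = n_genes, n_ntc = n_ntc, coverage = coverage,
                      depth = depth),
    seed = seed, ...
  )
}
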