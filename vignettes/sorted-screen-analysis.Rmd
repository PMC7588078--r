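---
title: "Scoring FACS-sorted CRISPRi screens with empirical false discovery control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring FACS-sorted CRISPRi screens with empirical false discovery control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
library(dplyr)
```

## The experimental design this package models

In a reporter-sorted CRISPRi screen, cells carrying a fluorescent
transcriptional reporter and dCas9-KRAB are transduced with a pooled sgRNA
library at a multiplicity of infection below one, so each cell silences at
most one gene. After pathway induction the reporter histogram is bimodal: a
large right-shifted peak of responding cells and a small left-shifted peak
of cells with little or no reporter expression. Cells are sorted into three
gates — "low" (below the valley between the peaks), and "medium"/"high" (the
responding peak split in half at its median) — and the sgRNA cassettes of
each fraction are amplified and sequenced. A gene whose silencing lowers
reporter output (a *positive regulator* of the pathway) shifts its cells
toward the low gate, enriching its sgRNAs there; a *negative regulator*
enriches in the higher gate.

`sortscreen` implements the complete downstream analysis — sgRNA counting,
per-sgRNA log2 fold changes, gene-level phenotype scores and significance,
empirical false-discovery control, and hit classification — together with a
generative simulator of the whole experiment, so that every stage can be
verified against known ground truth.

## The scoring model

For one pairwise comparison of sorted fractions (numerator always the
lower-fluorescence gate):

1. **Frequencies.** Counts are pseudocounted (default 1 read) and
   normalized to within-sample frequencies per library, because each
   sub-genome library carries its own non-targeting controls (NTCs).
2. **Fold changes.** Per sgRNA, `lfc = log2(freq_num / freq_den)`, then
   centered by subtracting the library's median NTC fold change. Centering
   makes the NTC distribution the origin; it is idempotent and configurable
   (`center = FALSE` turns it off).
3. **Epsilon.** The gene phenotype score is the signed mean of the gene's 3
   most extreme sgRNAs by absolute centered fold change (ties broken by
   sgRNA identifier). Averaging only the extreme 3 of 5 discounts inactive
   sgRNAs, whose knockdown fails; averaging with sign keeps epsilon
   interpretable — positive epsilon means enrichment in the lower gate,
   i.e. a positive regulator.
4. **Significance.** A two-sided Mann-Whitney U test compares the gene's
   sgRNA fold changes with all the library's NTC fold changes. The exact
   null distribution of U is used whenever the smaller sample has at most 8
   values and the combined sample is tie-free; otherwise the tie-corrected
   normal approximation (no continuity correction) is used. With 5 sgRNAs
   per gene the exact path is the norm; ties arise when two sgRNAs have
   identical count pairs.
5. **Hit strength.** `epsilon * -log10(p)`: a volcano plot's two axes
   multiplied, so a gene must be both strong and consistent to score.

### Empirical false discovery control

Because hit strength has no tractable null distribution, the null is built
empirically: "quasi-genes" are assembled by drawing 5 NTC sgRNAs with
replacement and scored exactly like real genes. The FDR at a threshold `t`
is the exceedance ratio

    FDR(t) = [Q(t) / N_Q] / [R(t) / N_R]

with `Q`, `R` the numbers of quasi and real scores at or above `t` in
absolute value. The selected cutoff is the smallest attained real value
whose FDR — and that of every larger attained value — stays below the
target (default 0.10). This monotone rule makes the accepted region a
single upper tail, and restricting candidates to attained real values makes
the search finite and exact. A single threshold serves both tails; the
regulator sign is recorded per gene.

Two design choices here were genuinely open:

* **Number of quasi-genes.** The default is 10 per real target. With a
  1:1 ratio the estimator's behaviour at the very top of the ranking is a
  coin flip: on a fully null screen the top-ranked real gene exceeds every
  quasi-gene with probability about `N_R / (N_R + N_Q)` = 1/2 by
  exchangeability, and whenever it does it is called a hit (its FDR
  estimate is exactly 0). At 10:1 that probability drops to about 9%, so a
  null screen typically returns zero hits while the added cost stays
  modest. `n_quasi` remains configurable.
* **Quasi-gene reference set.** A quasi-gene's members are themselves NTC
  values. If they are also left inside the Mann-Whitney reference, every
  quasi-gene ties with the reference and is forced onto the approximate
  p-value path while real genes take the exact path, which measurably
  skews the null hit-strength distribution. Since a real gene's sgRNAs are
  never part of its own reference, the package excludes each quasi-gene's
  member sgRNAs from its reference set, keeping the two score populations
  comparable.

### Three comparisons and hit classes

`run_all_comparisons()` scores `low_vs_high`, `medium_vs_high` and
`low_vs_medium`, each with its own seeded quasi null. The numerator is
always the lower gate, so a positive regulator has positive epsilon in all
three. (The medium-versus-low comparison is reported with `low` in the
numerator; this is the same comparison others may write as "medium vs low",
with all signs flipped.) Genes passing in `low_vs_high` are
**high-confidence** hits; genes passing only in a medium-involved
comparison are **putative** hits — these moderate phenotypes validate at a
lower rate, hence the separate label. A gene hit in several comparisons is
counted once, with high confidence taking precedence, so the classes
partition the hit list. `overlap_test()` quantifies the overlap of two hit
sets with the upper hypergeometric tail (one-sided Fisher's exact test),
computed in log space because genome-scale overlaps produce p-values far
below double-precision underflow thresholds on the linear scale.

Libraries target transcription start sites; `collapse_tss_to_gene()` keeps,
per gene, the TSS with the largest absolute hit strength (ties to the
smallest TSS identifier).

## The simulator: what it emulates and what it does not

`simulate_screen()` generates the experiment the analysis assumes:

* one sgRNA per cell, drawn uniformly (no bottlenecking — screens of this
  design report none; a custom abundance vector would be the extension
  point if needed);
* log10 reporter fluorescence as a two-component lognormal mixture: with
  probability `pi_off` a cell is a non-responder at `mu_off`, otherwise it
  sits at `mu_induced + activity * beta` with within-peak standard
  deviation `sigma`, where `beta` is the gene's effect (log10 shift under
  full knockdown, negative for positive regulators) and `activity` in
  [0, 1] is the sgRNA's knockdown efficacy;
* valley gating on a 256-point Gaussian-kernel density (Silverman
  bandwidth) between the two largest modes, falling back to a fixed
  quantile gate (default 0.15) with a warning if the smoothed histogram is
  unimodal; the remaining cells are split at their median with an exact
  partition (medium and high differ by at most one cell);
* multinomial sequencing of each fraction at fixed depth, so every count
  column sums to the depth exactly.

Default parameters, chosen once to match the modeled screen design:
5 sgRNAs per gene, 250 NTCs per library, coverage 100 cells per library
element per fraction (the total pool is `3 * coverage * library size`),
depth 2e6 reads per fraction, `mu_induced = 4.0` and `mu_off = 2.8` (a
16-fold separation, comfortably above the >8-fold reporter induction such
screens achieve, so the valley is well defined), `sigma = 0.25` log10
units (clearly resolved peaks at ~5 sigma separation), and
`pi_off = 0.15` (a small left-shifted peak). Ground-truth effect sizes for
spiked regulators default to magnitudes uniform on [0.6, 1.2] log10 units
— half to full blockade of induction — with sgRNA activities from
Beta(5, 1), i.e. mostly active sgRNAs with a tail of weak ones.

The simulator does **not** model puromycin selection dynamics, growth or
fitness effects, PCR amplification bias, sgRNA off-targets, sorter
impurity, or cell-cycle structure. Passing tests on simulated screens
therefore demonstrate that the statistics recover the effects the
generative model encodes at realistic noise levels — not that any
particular biological screen is free of those unmodeled artifacts.

## Numerical choices and degenerate inputs

* P-values are clamped to (0, 1]; `p = 1` gives hit strength exactly 0.
* Exact Mann-Whitney CDFs are computed once per sample-size pair and
  cached.
* All counts are validated as non-negative integers; count tables read
  against a library are completed with zero rows, since the statistics
  need the full row set.
* Ambiguous reads (several spacers at the minimal Hamming distance) are
  discarded rather than fractionally assigned, keeping counts integral and
  conservative; read qualities are ignored. The crop offset has no
  universal default — it depends on the vector and sequencing primers — so
  it is an explicit argument.
* An empty sorted fraction sequences to an all-zero column with a warning;
  gating requires at least 10 cells; identical-fluorescence populations
  fall back to the quantile gate and still partition exactly.
* Every stochastic stage takes a seed; `simulate_screen()` and
  `run_all_comparisons()` split one user seed deterministically across
  stages, making whole analyses reproducible to the byte.

## A worked example

A small screen with 15% spiked positive and 10% spiked negative
regulators:

```{r example}
cfg <- screen_sim_config(n_genes = 50, n_ntc = 50, coverage = 30,
                         depth = 1e5)
sim <- simulate_screen(cfg, seed = 3, fraction_positive = 0.15,
                       fraction_negative = 0.10)
ana <- run_all_comparisons(sim$counts, sim$library, seed = 2)
glance(ana)
```

```{r classify}
cls <- classify_hits(ana)
count(cls, confidence_class)

truth <- filter(sim$effects$gene_effects, beta != 0)
mean(truth$gene %in% ana$low_vs_high$hits$target)  # sensitivity
```

```{r volcano, fig.width = 6, fig.height = 4}
autoplot(ana$low_vs_high)
```

## Known limitations

* **The empirical null is built from a finite control pool.** All
  quasi-genes resample the same ~250 NTC fold changes, so conditional on
  one screen their score distribution carries the pool's own sampling
  deviations (of order `1/sqrt(250)`) coherently, and extreme targeting
  sgRNAs can fall outside the NTC range entirely (about `2N/(m+1)` of `N`
  targeting sgRNAs fall beyond the extremes of `m` controls, regardless of
  the noise distribution). Two consequences follow: a two-sample test
  comparing real and quasi score distributions on a null screen will
  reject more often than its nominal level, and the very top of the null
  ranking is slightly under-covered by the quasi null. This is a property
  of empirical nulls built from finite control pools, not of this
  implementation; more NTCs per library would shrink it.
* The Mann-Whitney test with 5 sgRNAs has a granular exact p-value floor;
  significance resolution below `2 / C(m + 5, 5)` is impossible.
* Scoring assumes one sorted replicate per fraction; there is no
  replicate-combination machinery.
* At the scale used in the package's verification suite (up to 2,000 genes,
  chosen so a full ten-seed study runs on a laptop), headline counts from
  genome-scale screens are not expected to reproduce numerically; the
  suite checks recovery, calibration and arithmetic, not published hit
  lists.
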