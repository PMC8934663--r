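---
title: "Position-specific mononucleotide features and the CRISPR-kp score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific mononucleotide features and the CRISPR-kp score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprkp)
```

## The problem

When a CRISPR-Cas9 ribonucleoprotein (RNP) pre-assembled with a dual-guide
RNA (crRNA + tracrRNA) is delivered into an embryo, the fraction of alleles
that end up carrying insertions or deletions — the indel frequency, in
percent — varies widely between guides targeting different sites, and much
of that variation is attributable to the target sequence itself. `crisprkp`
fits a simple, interpretable model of that dependence from a panel of tested
guides and uses it to score candidate guides.

The unit of data is a *guide set* ([`guide_set()`]): one crRNA per row with
its 20-nt protospacer (position 1 is the 5′ nucleotide), its 3-nt NGG PAM
(positions 21–23 of the full 23-nt target), an optional target-strand label,
and replicate indel-frequency measurements, typically produced by Sanger
trace decomposition tools (TIDE, ICE) run on pooled-embryo PCR amplicons.
Those decomposition tools are upstream of this package: their numeric output
is our input.

## The feature model

For each of the 92 cells of the 4 nucleotides × 23 positions grid,
`crisprkp()` asks a single question: are the guides carrying this nucleotide
at this position more or less efficient than the remaining guides? The
weight of a guide is its **mean** indel frequency across replicates — one
value per crRNA; replicates are never pooled as if they were independent
guides. The two groups are compared with a classical pooled-variance
two-sample Student's t test:

$$ t = \frac{\bar w_{\mathrm{in}} - \bar w_{\mathrm{out}}}
           {s_p\sqrt{1/n_{\mathrm{in}} + 1/n_{\mathrm{out}}}},
   \qquad \mathrm{df} = n_{\mathrm{in}} + n_{\mathrm{out}} - 2, $$

with a two-sided p-value. The cell's **signed score** is
$\operatorname{sign}(t)\cdot(-\log_{10} p)$: positive for *favored*
nucleotides (carriers are more efficient), negative for *disfavored* ones.
Within each position the four tests get Bonferroni-corrected significance
flags at 0.05/4 = 0.0125 and 0.01/4 = 0.0025.

Cells where either group has fewer than two guides, or where the pooled
variance vanishes with unequal means, are *undefined*: they carry `NA`
statistics and a signed score of 0, and flow through the pipeline silently.
The fixed GG at PAM positions 22–23 always produces eight such cells. A
fully degenerate cell with zero variance but *equal* means is treated as
carrying no signal (t = 0, p = 1) rather than as undefined, so a null data
set (all weights equal) yields a complete table of p = 1 everywhere.

The **CRISPR-kp score** of a candidate 23-nt target is the sum over
positions of the signed scores of the cells its nucleotides select
(`predict()` on the fitted model). All defined cells contribute, not only
significant ones: the score is a sum of log-evidence terms, and truncating
at a significance threshold would discard real (if individually weak)
signal. An `N` at PAM position 21 contributes 0; a concrete nucleotide
there contributes its cell like any other, since the N position varies in
the training input. Positions 22–23 contribute 0 by construction.

```{r example}
cfg <- kp_sim_config(
  effects = planted_effects(c(5, 16, 20), c("T", "C", "C"), c(20, 15, -15))
)
sim <- simulate_guides(cfg, seed = 1)
fit <- crisprkp(sim$guides)
fit
predict(fit, "ACGTTCGTACGTACGCACGAAGG")
```

## Design choices that were genuinely open

* **Pooled vs Welch variance.** The classical Student's test is the
  default; it is also the convention of weighted k-mer logo analyses this
  model follows, and at cohort sizes of ~50 guides the group sizes per cell
  are too small for Welch's df estimate to be stable. Welch is available
  via `crisprkp(..., var_equal = FALSE)`.
* **Two-sided p with the direction in the sign**, rather than a one-sided
  p. Favored and disfavored features are flagged symmetrically, and the
  sign already carries the direction. A one-sided mode
  (`alternative = "one.sided"`, which halves the two-sided p) is provided
  for strict emulation of logo tools that report the observed-direction
  tail. Because the choice rescales every $-\log_{10}p$ by the same
  monotone map, rankings of features are unchanged; score totals differ by
  roughly $\log_{10}2$ per defined position.
* **Per-guide means as weights.** One weight per crRNA keeps the df honest;
  replicate pools of the same injection are not independent observations of
  the sequence effect.
* **No correction across positions.** Only the per-position Bonferroni over
  the four nucleotides is applied; the 23 positions are reported as
  separate families, which is the convention these flags follow. Users
  comparing across positions should rely on the p-values themselves.
* **Strict class thresholds.** Activity classes count means strictly above
  75% and strictly below 25%; a guide at exactly the boundary is in neither
  class.

## Numerical choices

* p-values are floored at 1e-300 before the log transform, so signed scores
  stay finite.
* Group weights are sorted before the t statistic is computed, which makes
  the fitted table exactly (bit-for-bit) invariant under permutation of the
  input guides — floating-point summation order no longer depends on row
  order.
* Serialized tables render numerics with 17 significant digits, so the
  write/read pairs round-trip losslessly.
* `top_features()` excludes cells with p ≥ 1 (a null table ranks nothing)
  and breaks ties by position, then nucleotide, so rankings are
  deterministic.

## What the synthetic generator emulates — and what it does not

`simulate_guides()` draws protospacers uniformly and independently over
{A,C,G,T}²⁰ with a uniform PAM N, and builds a latent efficiency as

$$ \text{baseline} + \sum_{\text{matching cells}} \beta_{(\mathrm{pos},\,\mathrm{nt})} + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_{\text{guide}}), $$

with replicates adding $N(0, \sigma_{\text{rep}})$ noise, clamped to
[0, 100] by default. Defaults mirror a typical single-condition cohort of
this kind: 51 guides, 4 replicate pools, baseline 57%, guide-level SD 15
points, replicate SD 5 points; the effect table defaults to empty (a null
simulation). Uniform independent composition is deliberate: the feature
model is a per-position marginal model, and uniformity maximises per-cell
group balance at small n. One integer seed governs everything; each guide
gets its own deterministic substream, so guide *i* is reproducible
regardless of cohort-level vectorisation.

The generator is an additive-percent abstraction. It does **not** simulate
dinucleotide or genomic sequence structure, guide-RNA secondary structure,
chromatin context, Sanger-trace noise, dose–response, or mosaicism — and the
additive model itself is a package choice, not an empirical claim. Passing
recovery and calibration tests therefore demonstrates that the statistics
behave correctly *under this model*; they do not certify predictive
performance on real guides, which must be established on measured data.

## Evaluation utilities

`evaluate_guides()` bundles the dataset-level summaries used to
characterise a cohort: mean efficiency, activity-class counts, GC content
of positions 1–20 (the PAM is excluded) against efficiency, a pooled
two-sample strand test (sense vs antisense targets), optional
cross-condition correlations on name-matched guides, and Spearman
benchmarking of external design-tool score columns (`compare_tools()`).
Tool scores are consumed as a provided table; no external service is
called. Correlations of CRISPR-kp scores with the model's own training
cohort are labelled *in-sample* in the report — validation belongs on an
independent set.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the pipeline at the scale the
generator defaults describe: training cohorts of 51 guides, held-out
cohorts of 27, null calibration over 200 simulated cohorts
(≈ 16 800 defined cells, Kolmogorov–Smirnov distance from uniform), and
power/recovery over 100 runs at n = 200 with a +40-point planted effect
against 10-point noise. These sizes give stable Monte-Carlo estimates while
the whole suite stays fast.

## Limitations

* Mononucleotide (k = 1) features only; k ≥ 2 motifs, secondary structure
  and off-target effects are out of scope.
* The t test assumes approximately normal, equal-variance weights within a
  cell's two groups; percent efficiencies near the 0/100 boundaries violate
  this, and the clamped generator reproduces that honestly rather than
  hiding it.
* CRISPR-kp totals are sums of dependent evidence terms (each guide enters
  many cells), so they are a ranking device, not calibrated probabilities.
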