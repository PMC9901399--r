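---
title: "Differential co-expression testing: models, permutation schemes and design choices"
author: "dcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression testing: models, permutation schemes and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcoex)
```

## The model

`dcoex` tests, pair by pair, the hypothesis that the correlation of two
molecules' expression is the same in two sample groups. Expression values
are assumed already normalised and log-scaled; the test sees only their
within-group correlations. Writing `r_A`, `r_B` for the sample correlations
in groups of sizes `K` and `L`, the Fisher transform `z(r) = arctanh(r)` of
a correlation computed from bivariate-normal data is asymptotically normal
with mean `arctanh(ρ)` and variance

* Pearson: `1/(M − 3)` — free of the unknown ρ;
* Spearman: `(1 + ρ²/2)/(M − 3)` — depends on ρ, but boundedly so.

Under `ρ_A = ρ_B` the standardised difference

$$Z = \frac{\operatorname{arctanh}(r_A) - \operatorname{arctanh}(r_B)}
          {\sqrt{\sigma^2(K) + \sigma^2(L)}}$$

is asymptotically standard normal. For Spearman the package substitutes the
worst-case factor 1.5 for `1 + ρ²/2` directly **in the statistic** (not only
in the p-value), for two reasons: the resulting normal tail provably
upper-bounds the plug-in p-value for every ρ, and analytic and permutation
modes then share one statistic, so their outputs are directly comparable.
`ztestStatistic(..., spearmanMode = "plugin")` exposes the plug-in version;
the test suite verifies the bound on randomly drawn configurations.

Spearman correlations are Pearson correlations of within-group midranks
(average ranks on ties); ranks are recomputed inside each group and inside
every permutation relabeling.

### Sidedness

Differential co-expression is a two-directional question — a regulator can
lose or gain correlation — and downstream classification uses both
directions, so the default p-value is two-sided, `2Φ(−|z|)`. A one-sided
option (`one_sided_greater`, alternative "correlation larger in group A")
is provided for directional hypotheses.

### Degenerate inputs

* Groups of three or fewer samples make the `1/(M − 3)` variance undefined
  and are rejected when the `CoexExperiment` is constructed, not later.
* A molecule that is constant within a group has no defined correlation;
  this is a hard error naming the molecule and the group rather than a
  silent `r = 0`.
* Correlations with `|r| ≥ 1 − 10⁻¹²` (perfectly collinear input, or the
  near-unity blocks of the synthetic designs) are clamped to
  `±(1 − 10⁻¹²)` before `arctanh`. The exported `fisherTransform` warns;
  the permutation engine clamps silently, since a warning per relabeling
  carries no information.

## Permutation p-values

The asymptotic normal approximation needs sample sizes that real designs do
not always have, so every statistic can instead be referred to its label
permutation distribution: reassign the `K + L` samples to the two groups
uniformly at random with sizes preserved, recompute `Z`, repeat `B` times.

The defining choice is **what is compared to what**. `dcoex` compares each
pair's observed `|z|` only against that same pair's permuted values
(`perPairPermutationPvalues`). The alternative of pooling all pairs'
permuted statistics into one reference distribution
(`pooledPermutationPvalues`) is kept as a comparator because it is used by
other tools; it is only valid when the pairs are exchangeable. When most
pairs change strongly and one changes weakly, the pooled null is dominated
by the strong pairs' large statistics and the weak pair's p-value is pushed
upwards — `permutationComparisonStudy()` reproduces this failure mode (see
below).

Conventions, each chosen once:

* `p = (1 + \#\{b : |z^{(b)}| \ge |z^{(0)}|\})/(B + 1)`. The add-one
  smoothing keeps p strictly positive (minimum `1/(B+1)`), which BH
  adjustment requires; `smoothed = FALSE` restores the raw proportion.
* Ties count as exceedances (`≥`), the conservative direction.
* One seeded RNG stream drives all relabelings, and a relabeling is applied
  to the whole matrix, so all pairs (and the aggregation scores) share one
  permutation set — this is what physically reshuffling sample labels
  means, and it makes pair-level and score-level outputs mutually
  consistent. The caller's RNG state is saved and restored.
* With `R` hypotheses BH-adjusted at level `α`, the default
  `B = ceiling(R/α)` (`minPermutations`) is the smallest count whose
  granularity can resolve an adjusted rejection at `α`.
* The engine is single-threaded vectorised R; a `workers` configuration key
  is accepted for interface compatibility but does not affect results,
  which are therefore trivially independent of worker count.

## Aggregation scores

A regulator whose many interactions each change a little can be invisible
to the pair-level test after multiple-testing adjustment. Two summaries are
computed per source molecule over exactly its network-listed targets (in
exhaustive mode: all other molecules):

* **Hypergeometric overrepresentation**: with `S` significant changes among
  `N` interactions overall, a source with `n_G` interactions and `s_G`
  significant ones is scored by `P(X ≥ s_G)`, `X ~ H(N, S, n_G)`. The upper
  tail includes the observed value; significance is `adjusted p < α` on the
  pair level, with BH re-applied across sources.
* **z-score summaries**: mean, median or a quantile (type-7
  linear-interpolation convention) of the source's z statistics, tested
  against zero by the same label permutation stream as the pair-level test.
  A single-target source therefore reproduces its pair's permutation
  p-value exactly — a degeneracy the tests assert.

## The synthetic designs

Two generators produce the validation datasets; they are first-class,
tested code, and their defaults are the study's design points.

**Hub design** (`generateAggregationDataset`): `m` genes (default 1000),
`n` samples per group (default 20), zero means, unit variances. Gene 1
correlates `+ρ` (default 0.5) with genes `2..k` (default `k = 100`) in
"Normal" and `−ρ` in "Tumor"; all other genes are independent. The matrix
with exactly those entries and zeros elsewhere is **indefinite** whenever
`(k−1)ρ² > 1` — including the default design point — so the correlations
are realised by the single-factor construction
`gene_j = ±ρ·gene_1 + \sqrt{1−ρ^2}·ε_j`, which reproduces every stated
hub–gene correlation exactly, adds a common `ρ²` correlation among genes
`2..k` (identical in both groups, hence invisible to the hub's tested
pairs), and is positive definite for every `k` and `|ρ| < 1`. `ρ = 0` or
`k = 1` give exact nulls.

**Paired-blocks design** (`generatePermDataset`): `2m` genes in `m`
independent pairs; "Normal" (size `K = 100`) has identity covariance,
"Tumor" (size `L`) is block-diagonal with `k` strong blocks (within-pair
correlation 1, clamped to `1 − 10⁻⁶` so the covariance stays positive
definite for sampling) and `m − k` weak blocks (correlation 0.5). The last
pair is the flagged weakly-changed pair on which the two permutation
schemes are compared.

The drivers `aggregationPowerStudy()` (10 replicates per cell by default)
and `permutationComparisonStudy()` (20 replicates, `L` from 10 to 100)
report mean and standard deviation of the relevant p-values per grid cell.
The per-curve ρ grid of the power study defaults to {0.3, 0.5, 0.7}; sample
sizes are per group. The acceptance checks run the hub design at its
defaults with `B = 1000` permutations and the paired-blocks contrast at
`L ∈ {40, 50, 60, 70}` — sizes chosen so the full suite completes in a few
minutes on one CPU while leaving the conclusions comfortably clear of
their thresholds.

What the generators deliberately do **not** model: library-size
(compositional) coupling between molecules, count noise, outliers, or
non-normal margins. Passing tests therefore demonstrate correctness of the
statistics under the stated multivariate-normal models, not robustness to
every artefact of real sequencing data — the permutation mode exists
precisely because real data violate the analytic assumptions.

## The isomiR application layer

The helpers mirror a miRNA-isoform workflow: 5′-isomiR names are
`name|shift` with an explicit sign for nonzero shifts (`parseIsomir` /
`formatIsomir` round-trip canonically); counts are RPM-normalised against
per-sample library sizes; the highly-expressed set is the minimal prefix of
molecules — ranked by read share pooled across all samples, ties broken by
identifier — covering 95% of reads; RPM values are multiplied by the
sample's AGO2 expression (proportionality constant 1 — correlations are
computed within one isomiR, so the constant cancels, and a constant AGO2
vector is an exact no-op for rank correlations) and `log2(x + 1)`
transformed. Anticorrelation networks keep pairs with `r < −0.3` (strict:
the boundary value is excluded), and a significantly changed pair
(BH-adjusted `p < 0.05`) is classified `lost` when it is anticorrelated in
"Normal" but not "Tumor", `gained` in the reverse case — the three statuses
partition the tested pairs, and per-source counts (optionally normalised by
the "Normal"-state target number) come from `summariseTargetChanges`.

Note the compositional caveat above: when a handful of isomiRs dominate a
small library, their RPM values are negatively coupled by construction, and
a shared AGO2 factor couples them positively; the package computes what is
asked on the values given and leaves such design concerns to the analyst.

## Known limitations

* The analytic Spearman p-value is an upper bound, i.e. deliberately
  conservative; exact calibration at small `n` comes from the permutation
  mode.
* The permutation engine materialises the `B × R` matrix of permuted
  statistics; for exhaustive mode on thousands of molecules, prefer the
  analytic mode or a predefined network.
* Group labels are exchangeable under the null only if samples are
  independent; paired or batch-structured designs need upstream handling.
* The `−0.3` threshold and the 95% coverage fraction are conventions of the
  application field, exposed as parameters rather than validated choices.
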