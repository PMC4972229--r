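---
title: "Downscaled complementarity: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaled complementarity: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Complementarity-based prioritization needs a species inventory for every
candidate site. In practice inventories exist as coarse atlases (say,
50 × 50 km cells) or range maps, while planning happens on much finer cells
(say, 10 × 10 km). `dscomp` treats the coarse data as a training signal for
a fine-scale priority score:

1. **Complementarity at coarse grain.** Each coarse cell gets a
   rarity-weighted richness value, RWR = Σ 1/c_i over the species present,
   where c_i is the number of cells species i occupies. RWR is a static
   score, cheap to compute, and in rank order tracks the cell removal order
   of iterative reserve-selection heuristics closely.
2. **Transfer to fine grain.** Either *statistically* — regress coarse RWR
   on per-cell environmental summaries and evaluate the fitted model on the
   same variables measured in fine cells — or *directly* — rasterize range
   maps onto the fine grid and compute RWR from the overlap counts
   themselves.
3. **Evaluation.** The surrogate is only as good as the sites it picks.
   Accumulating fine cells in surrogate order and counting represented
   species yields S; the Species Accumulation Index
   SAI = (S − R)/(O − R) locates S between the mean random accumulation R
   and a (near-)optimal accumulation O. SAI is evaluated at 15–35% of the
   landscape in 5% steps and summarized by the mean; an area-under-curve
   mode is available as an option.

The key assumption of statistical downscaling is that the environmental
drivers of complementarity operate similarly at both grains, so a function
fitted across coarse cells remains meaningful when evaluated at fine cells.
Nothing enforces this; the evaluation machinery exists precisely to measure
how far the assumption carries.

## Parameters that matter

* `n_trees = 500` regression trees, each grown on a bootstrap sample of
  `sample_fraction = 0.66` of the coarse sites drawn **without**
  replacement; the held-out ~34% per tree provides the out-of-bag error,
  OOB R², and permutation importances (reported as the raw mean increase in
  OOB error after permuting a predictor, not normalized). Ensemble error
  typically plateaus well before 200 trees, so a warning is emitted below
  that count. Fits are reproducible given `seed`.
* Predictor selection (`vrfa_select`): principal factors of the correlation
  matrix, Kaiser criterion (eigenvalue > 1), Kaiser-normalized varimax
  rotation, then the variable with the largest absolute loading per factor.
  Principal-component extraction is used rather than maximum-likelihood
  factoring, matching the eigenvalue-based retention rule. With only a
  handful of mutually independent predictors (as in the synthetic
  landscapes) this reduction is unnecessary, and the pipeline accepts an
  explicit predictor list; the end-to-end tests fit on all generated
  variables for that reason.
* SAI: protection fractions default to 0.15, 0.20, 0.25, 0.30, 0.35;
  R is the pointwise **mean** accumulation over `n_reps = 1000` uniformly
  random orderings (its pointwise standard deviation is retained and
  serialized for uncertainty reporting; per-replicate SAI quantiles are not
  computed).
* O is estimated by the reverse-greedy core-area ranking by default; the
  static-RWR estimate is always computed alongside and serialized, because
  the two are empirically often identical but not provably so.
* `dutilleul_test`: 12 equal-width Euclidean distance classes spanning
  distances up to half the maximum pairwise distance; more distant pairs
  are treated as uncorrelated. The effective sample size comes from the
  trace formula M = 1 + tr(BΣx)tr(BΣy)/tr(BΣxBΣy) on the class-estimated
  covariance matrices; t = r√((M−2)/(1−r²)) with M − 2 degrees of freedom,
  two-sided. The class scheme is configurable since the estimator itself
  leaves it open.

## Numerical and tie-break choices

* **Site-ID tie-break.** Score-based rankings sort by descending score with
  ties broken by ascending site ID (bytewise, locale-independent), making
  every ranking a deterministic total order.
* **Core-area removal tie-break.** At each removal step the cell with the
  smallest marginal loss δ = max over its species of 1/(remaining occupied
  cells) is removed. With presence–absence data δ only takes reciprocals of
  integers and ties are pervasive — near the end of a run most remaining
  cells hold a last copy of something and tie at δ = 1 — so removal among
  tied cells is decided by the smallest *remaining* rarity-weighted
  richness (the least-complementary of the equally expendable cells), and
  only then by site ID. Purely lexicographic tie-breaking makes the
  heuristic effectively arbitrary at small prefix sizes: on random 12-site
  instances its top-m sets fell up to 4–5 species short of the exhaustive
  optimum, whereas with the RWR tie-break they stay within 1 species at
  m ≤ 3 across the tested families (verified against exhaustive
  enumeration; see the test suite). The rank value reported per cell is
  (removal position)/(number of cells), so values near 1 mark cells kept
  longest.
* **Fraction to cell count.** round half up, minimum one cell.
* **Degenerate SAI.** Fractions where O = R carry no signal; they are
  flagged NA, excluded from the mean, and warned about.
* **Predictions** are clamped at zero (tree averages of a nonnegative
  response cannot go negative, but the clamp documents the invariant);
  sites with missing predictor values are dropped from fits and flagged in
  predictions, never imputed.
* **Degenerate spatial covariance.** If the estimated trace denominator of
  the modified t-test is nonpositive or nonfinite, the test falls back to
  the classic t-test with a warning. The effective sample size is clamped
  to [2, n].
* **Zero-occurrence species** are excluded from rarity, ranking, and
  accumulation everywhere, and reported.

## The synthetic landscape generator

`gen_landscape()` emulates the structure of a nested atlas setting at desk
scale. Defaults: 50 × 50 fine grid, block factor 5 (10 × 10 coarse grid),
60 species, 10 environmental variables, smoothness 6 (Gaussian kernel SD in
cells), β = 1, ε = 0.25, rarity skew 1.5, dilation radius 1.

* **Environment:** each variable is a smoothed Gaussian field plus a small
  independent nugget, standardized over fine cells. Coarse tables hold
  block means. Block *ranges* are not generated: at the generator's native
  resolution a fine cell has no internal range, so a range-type predictor
  could never transfer across grains.
* **Occupancy:** each species responds to 1–2 variables through a Gaussian
  suitability kernel with a random optimum (drawn from the
  `optimum_quantiles` window, default the 5–95% range) and tolerance; its
  occupancy score is β·suitability + ε·noise, and it occupies exactly its
  target number of cells (the highest-scoring ones). Targets follow a
  log-series-like skewed distribution, so most species are narrow-ranged
  and a few are widespread, and every species occupies at least one cell by
  construction. The noise term makes the coarse-to-fine transfer imperfect
  by design — exactly the imperfection the SAI measures. Narrowing
  `optimum_quantiles` to one end of a single driver variable concentrates
  every species there and makes RWR monotone in that gradient; this
  constructed-signal setting is how the tests verify that the downscaling
  model recovers a known driver (top permutation importance, fine-scale
  Spearman ≥ 0.8).
* **Range maps:** each species' mask is its occupied cell set dilated by a
  disc (radius 1 cell by default), so masks always cover true occupancy and
  never under-cover. The default radius was calibrated so that mask-implied
  per-cell richness exceeds true richness by a factor of about 1.5–3,
  matching the over-estimation reported for interpreting real range maps at
  fine resolutions (radius 2 produced 3.3–4.2×, outside that band).

What the generator does **not** emulate: dispersal limitation and spatial
range cohesion beyond environmental clumping, phylogenetic structure,
coastlines/islands and irregular grids beyond partial edge blocks,
observation effort, and false presences. Passing tests on these landscapes
show the machinery is correct and that environment-driven signal is
recoverable; they do not show that any particular real atlas downscales
well.

## Problem sizes used by the tests

Module tests run on 20 × 20 fine grids (k = 4, 15 species); end-to-end
properties use the default 50 × 50 landscape. The surrogacy sign test runs
the full pipeline over 20 seeds (and 20 more with environment replaced by
unrelated white noise, where mean SAI is statistically indistinguishable
from 0). The modified t-test is calibrated with 1000 replicates of
independent fields on a 20 × 10 grid (empirical type-I error within the
binomial 99% interval of 0.05) and the exhaustive-optimum comparisons use
12-site instances, where enumeration is exact. The whole suite completes in
about a minute on a single core.

## Known limitations

* The static-RWR estimate of O can fall more than one species short of the
  exhaustive optimum at very small prefixes on sparse, species-rich
  matrices; the reverse-greedy estimate with the RWR tie-break is the
  default for this reason.
* Representation targets beyond one occurrence per species, species
  weights, site costs, and connectivity are out of scope.
* Range-map input is cell-ID lists only; polygon overlay (and hence map
  projections and geodesic areas) is not implemented.
* The RWR response is fitted on its raw scale; no transform is applied
  before regression.
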