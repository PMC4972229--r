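# dscomp — downscaled complementarity for conservation prioritization

Systematic conservation planning ranks sites by *complementarity*: how many
otherwise-unrepresented species a site adds to the sites already selected.
Computing complementarity needs species inventories of every candidate site,
but wall-to-wall inventories only exist at coarse grain — continental atlases
(e.g. 50 × 50 km cells) and global range maps — while planners must
prioritize much smaller sites. `dscomp` implements **downscaled
complementarity**: measure complementarity on the coarse grid, transfer it
to the fine grid, and use the transferred scores as a surrogate for the fine
inventories nobody has. It also ships the complete machinery needed to score
*any* surrogate against a true fine-scale inventory.

## The quantities at the core

**Rarity-weighted richness (RWR).** Species *i* occupying *c_i* cells has
rarity 1/*c_i* (a single-cell endemic scores 1/1 = 1; a species in 20 cells
scores 1/20 = 0.05). A cell's complementarity value is

RWR = Σ_i 1/c_i over the *n* species present in the cell,

so each species contributes exactly 1 in total across all cells.

**Surrogate construction.**

* *Statistical downscaling* (`SDC_a` from atlas data, `SDC_r` from range
  maps rasterized at coarse grain): fit a random-forest regression of
  coarse-cell RWR on environmental predictors (500 trees, ~66% of sites per
  tree, out-of-bag error and permutation importance), after reducing the
  candidate predictors with a varimax-rotated factor analysis (Kaiser
  criterion, one variable per retained factor). Apply the model to the same
  predictors measured in fine cells to get downscaled RWR.
* *Direct downscaling* (`DDC_r`): overlay the range maps on the fine grid
  and compute RWR straight from the overlap pattern.

**Evaluation.** Accumulate fine cells in surrogate order and count
represented species (S); compare against the optimum ordering (O, from a
Zonation-style reverse-greedy core-area ranking, with a static-RWR ranking
computed alongside) and the mean of 1000 random orderings (R), at 15, 20,
25, 30, 35% of the landscape. The **Species Accumulation Index**

SAI = (S − R) / (O − R)

is 1 for an optimal surrogate, 0 for random performance, negative if worse
than random; the point estimate is the mean over the five protection
levels. Agreement between surrogates and true complementarity is quantified
by Pearson correlations with significance from **Dutilleul's modified
t-test**, which replaces the sample size by an effective sample size
estimated from the spatial autocovariance of both variables.

## Worked example

The package includes a synthetic-landscape generator (nested 50 × 50 fine /
10 × 10 coarse grids, environment-driven occupancy, over-covering range
maps) so the whole pipeline runs without external data:

```r
library(dscomp)

# the textbook three-cell example: c = (1, 2, 1)
m <- matrix(c(1,1,0, 0,1,0, 0,0,1), nrow = 3, byrow = TRUE,
            dimnames = list(c("A","B","C"), c("sp1","sp2","sp3")))
rwr(occurrence_matrix(m, "coarse"))$score
#> [1] 1.5 0.5 1.0

land  <- gen_landscape(landscape_config(seed = 1))
model <- fit_downscale_model(land$occ_coarse, land$env_coarse, seed = 1)
pred  <- predict_fine(model, land$env_fine)          # SDC_a per fine cell

S <- accumulation_curve(ranking_from_scores(pred, land$occ_fine), land$occ_fine)
O <- optimum_curve(land$occ_fine, "zonation")
R <- random_mean_curve(land$occ_fine, n_reps = 1000, seed = 1)
sai(S, O, R)
#> Species Accumulation Index  (surrogate S:SDC_a vs O:zonation, R over 1000 reps)
#>  fraction   m  S  O      R   SAI
#>      0.15 375 44 60 41.288 0.145
#>      0.20 500 50 60 44.002 0.375
#>      0.25 625 54 60 46.224 0.564
#>      0.30 750 59 60 48.058 0.916
#>      0.35 875 59 60 49.581 0.904
#> Mean SAI (fractions): 0.581
```

So on this landscape the downscaled surrogate recovers 58% of the gain an
optimal selection achieves over random site selection, despite the
random-forest fit itself explaining little pointwise variance — ranking
quality, not regression fit, is what the index rewards. Correlation with
true fine-scale complementarity, corrected for spatial autocorrelation:

```r
dutilleul_test(pred$score, rwr(land$occ_fine)$score,
               coords = fine_coords(land$grid))
#> 	Dutilleul's modified t-test of association
#> t = 5.4867, df = 1710.5, p-value = 4.71e-08
#> sample estimates:
#>     cor
#> 0.13151
```

The same pipeline is scriptable from a shell via
`inst/cli/dscomp.R` (subcommands `simulate`, `downscale`, `evaluate`,
`rwr`, `rank`; exit codes 0/2/3 for success / validation error / runtime
error).

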