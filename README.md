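# teecology

Tools for studying the **genomic ecology of transposable elements (TEs)**:
what features of a TE copy and of its genomic neighbourhood predict how long
it survives in a genome. The package is aimed at plant and TE genomicists
who have a structural TE annotation (with nested insertions), per-copy age
information, and the usual layers of genomic context — methylation,
chromatin accessibility, expression, recombination, polymorphism — and want
a reproducible path from those layers to an interpretable model of TE age.

## What it computes

**Nesting resolution.** TE insertions frequently land inside older copies.
`resolve_nesting()` assigns every annotated base to exactly one copy — the
latest-arriving copy covering it, with arrival order read from the nesting
topology — and flags copies left with fewer than 50 bp as dropped. The
result is a base-pair-exact, disjoint segment set per copy.

**Two insertion-age estimators.** For LTR retrotransposons, the two LTRs
are identical at insertion, so their divergence measures age:
`k2p_divergence()` computes the Kimura two-parameter distance

&nbsp;&nbsp;&nbsp;&nbsp; *d* = −½ ln[(1 − 2P − Q) √(1 − 2Q)]

from the transition (P) and transversion (Q) proportions, and
*T* = *d* / 2μ with μ = 3.3 × 10⁻⁸ substitutions · site⁻¹ · year⁻¹. For all
orders, `terminal_branch_ages()` reads each copy's terminal branch length
*b* from a per-superfamily phylogeny and dates it as *T* = *b*/μ.

**Genomic-environment features.** Base composition and methylatable-context
densities (CG/CHG/CHH, counted on both strands) in the TE and its 1 kb
flanks; distance to the closest (and closest syntenic) gene; recombination
rate in cM/Mb from a monotone fit to a genetic map; MNase-hypersensitivity
counts and proportions; segregating-site densities; subgenome assignment;
methylation metaprofiles (TE body + 20 flanking 100 bp windows per side,
family-mean imputation); family expression per copy in RPM and the tissue
specificity index τ = Σᵢ(1 − xᵢ/x_max)/(n − 1).

**Survival model.** `fit_age_model()` trains a 1000-tree random-forest
regression of copy age on the assembled features (missing coded −1, family
capped at the 31 largest levels plus "smaller", 50 % train / 50 % test),
and the interpretation suite reports permutation importance (MSE increase,
scaled by its standard deviation, and as an RMSE increase in kya), category
aggregation, per-family Pearson correlations with age, and individual
conditional expectation (ICE) curves over the central 95 % of each feature.

**Synthetic data.** `generate_dataset()` builds a fully self-consistent toy
genome — 13 superfamilies, nested insertions with known arrival order,
sequences diverged under a K80 process at a known μ, and every context
layer — so the whole pipeline can be validated by recovery against known
truth, with no external downloads.

## A worked example

```r
library(teecology)
library(dplyr)

ds <- generate_dataset(sim_config(seed = 1))
write_dataset(ds, "toy/inputs")

res <- run_pipeline(pipeline_config(
  input_dir = "toy/inputs", output_dir = "toy/out",
  seed = 1, n_trees = 1000
))

glance(res$model)
#> # A tibble: 1 × 6
#>   n_trees n_train n_test       mse_test rmse_test_kya variance_explained
#>     <dbl>   <int>  <int>          <dbl>         <dbl>              <dbl>
#> 1    1000      95     95 128419995245.          358.               0.364

head(tidy(res$importance), 3)
#> # A tibble: 3 × 5
#>   term           delta_mse importance delta_rmse_kya zero_variance
#>   <chr>              <dbl>      <dbl>          <dbl> <lgl>
#> 1 family      64431631796.       6.17          80.8  FALSE
#> 2 superfamily 14082883570.       7.41          19.1  FALSE
#> 3 p_cg_te      2506643304.       1.88           3.48 FALSE
```

The model explains 36 % of age variance on the held-out half of this toy
genome, and permuting the family label costs about 81 kya of prediction
accuracy (RMSE) — TE taxonomy carries most of the signal, with TE base
composition (CG-context density, GC) next, mirroring how such models behave
on real maize data. `plot_ice(res$ice$length_bp)`,
`plot_importance(res$importance)` and `plot_methylation_profile()` draw the
corresponding figures.

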