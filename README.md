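# clgc — climate-change landscape genetics and connectivity

`clgc` is an R package for asking what projected climate change does to a
species' climatically suitable range, to the dispersal corridors linking
its populations, and to the genetic variation and genetic clusters those
populations carry. It is aimed at landscape geneticists and conservation
biologists who have climate rasters, occurrence records, microsatellite
genotypes and/or organellar haplotype sequences, and want the full chain —
species distribution models through genetic projection — as reproducible,
scriptable R instead of a string of GUI tools.

## What it computes

* **Ensemble SDMs**: correlation pruning (|r| ≤ 0.75), spatial rarefaction,
  pseudo-absence sampling, a multi-algorithm roster trained on repeated
  stratified 75/25 splits, retention gated on held-out AUC > 0.6 **and**
  TSS > 0.6 (TSS = sensitivity + specificity − 1), ensemble averaging,
  lowest-presence-threshold (LPT) binarization, and range-shift accounting
  with cos(latitude)-weighted areas in km².
* **Connectivity**: friction = (1 − suitability) + ε; accumulated-cost
  surfaces, least-cost paths and pairwise resistance matrices on the
  8-connected raster graph; all-pairs and shared-haplotype networks.
* **Diversity**: per-population I = −Σp ln p, Ne = 1/Σp², He = 1 − Σp²,
  and for sequences Nh, gene diversity h = n(1 − Σq²)/(n − 1) and
  nucleotide diversity π; pairwise Weir–Cockerham θ linearized as
  F/(1 − F); persistence projection that drops populations whose future
  suitability falls below the LPT and recomputes everything on the
  survivors.
* **Matrix tests**: Mantel and partial Mantel permutation tests
  (p = (count + 1)/(n_perm + 1), exhaustive enumeration when n! ≤ n_perm).
* **Climate-covariate admixture**: a logistic-normal ancestry regression
  Q = softmax(βx + γs + ε) fitted by MCMC with Gibbs data augmentation,
  DIC-based selection over a ladder of K, projection of ancestry under
  future climates, and per-cluster turnover reports.
* **Genetic landscapes**: pairwise distances at spherical midpoints,
  k-nearest-neighbour IDW interpolation (power 2, 12 points) clipped to
  the sample hull, and a penalized-spline GAM of interpolated divergence
  on suitability change.
* **Synthetic data**: seeded Gaussian-random-field climates, occurrences
  from a known logistic suitability, climate-driven ancestral clusters
  emitting SSR genotypes and chloroplast haplotypes, and an
  isolation-by-resistance drift option — so the entire pipeline is testable
  without any external data.

The methods vignette (`vignettes/landscape-genetics-pipeline.Rmd`)
documents the models, parameter defaults, numerical choices and
limitations.

## A worked example

The test-scale profile (20×20 grids, 10 populations, 500 MCMC sweeps)
runs the whole pipeline in a few seconds:

```r
library(clgc)
cfg <- defaultPipelineConfig("test", seed = 5)
state <- runPipeline(cfg)

state$range_shift$percent_change
#> [1] -14.68
round(state$range_shift$areas_km2[c("stable", "contraction", "expansion")])
#>      stable contraction   expansion
#>      458946       98041       16269
c(r = state$mantel$current$r, p = state$mantel$current$p)
#>     r     p
#> 0.491 0.005
state$dic_table
#>   K seed      DIC
#> 1 1 7079 2584.286
#> 2 3 7099 2055.680
round(state$turnover$overall_r, 2)
#> [1] 0.84
head(state$diversity[, c("pop", "N", "I", "Ne", "He", "h", "pi", "Nh")], 3)
#>   pop N     I   Ne    He     h      pi Nh
#> 1 P01 6 0.577 1.67 0.345 0.800 0.00160  4
#> 2 P02 6 0.804 2.11 0.431 0.933 0.00187  5
#> 3 P03 6 0.791 2.19 0.429 0.867 0.00173  4
```

Read: under the synthetic future climate the modelled range contracts by
14.7% (98,041 km² lost, 16,269 km² gained); linearized Fst correlates with
landscape resistance (Mantel r = 0.49, p = 0.005); DIC prefers the true
three-cluster model over a single cluster; the projected ancestry matrix
correlates at 0.84 with the current one (so spatial genetic structure is
reorganized but not erased); and the per-population table gives the usual
diversity statistics. Every stage also writes CSV/JSON/ASCII-grid products
plus a seeded manifest into `state$outdir`.

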