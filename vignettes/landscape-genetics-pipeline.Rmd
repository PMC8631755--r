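---
title: "Projecting climate-change impacts on range, connectivity and genetic structure with clgc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting climate-change impacts on range, connectivity and genetic structure with clgc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clgc)
```

## The analysis

`clgc` chains the standard components of a climate-change landscape-genetics
study into one seeded pipeline. The question it addresses is how projected
climate change reshapes (i) a species' climatically suitable range, (ii) the
dispersal corridors connecting its populations, (iii) the genetic diversity
those populations carry, and (iv) the spatial distribution of its genetic
clusters. The stages are:

1. **Ensemble species distribution modelling.** Climate layers are pruned at
   a pairwise Pearson cut (|r| ≤ 0.75 by default), occurrences are
   spatially rarefied, pseudo-absences drawn, and a roster of presence/
   absence algorithms (GLM, penalized-spline GAM, random forest,
   classification tree, linear discriminant, optionally a neural net and a
   surface range envelope) is trained on repeated stratified 75/25 splits.
   Models are retained only when held-out AUC **and** maximized TSS exceed
   0.6; the ensemble prediction is the (optionally TSS-weighted) mean of
   retained models. Suitability maps are binarized at the **lowest presence
   threshold** (LPT), the minimum predicted suitability over training
   presences, so every training presence stays inside the binary range.
2. **Range-shift accounting.** Per-cell categories
   (expansion/contraction/stable/absent) with spherically weighted areas,
   `area = (cellsize · 111.195 km)² · cos(lat)`.
3. **Least-cost connectivity.** The *continuous* suitability map is
   inverted into a friction surface, `cost = (1 − suitability) + ε` with
   ε = 0.001, and accumulated-cost distances and least-cost paths are
   computed on the 8-connected raster graph with endpoint-mean edge costs
   and √2 diagonal scaling (the gdistance/ArcGIS convention). Two networks
   are built: all population pairs ("population connectivity") and only
   pairs sharing a chloroplast haplotype ("genetic connectivity").
4. **Diversity statistics.** Per population: Shannon's information index
   I = −Σ p ln p, effective alleles Ne = 1/Σp², expected heterozygosity
   He = 1 − Σp² (GenAlEx convention, no small-sample correction; the
   unbiased uHe is emitted alongside), and for sequences the haplotype
   count Nh, Nei's gene diversity h = n(1 − Σq²)/(n − 1) and nucleotide
   diversity π (mean pairwise mismatch proportion, gap sites excluded
   pairwise). Populations under 5 genotyped individuals are dropped from
   SSR reporting to avoid underestimating Ne. Pairwise divergence is
   Weir–Cockerham θ (multilocus ratio of sums), linearized as
   F/(1 − F) for matrix regression.
5. **Matrix tests.** Mantel and partial Mantel permutation tests of
   linearized Fst against landscape resistance, with great-circle distance
   partialed out. Rows and columns of the second matrix are permuted
   jointly; the one-tailed p-value is (count + 1)/(n_perm + 1), switching
   to exhaustive enumeration (exact proportion over all n! relabelings)
   whenever n! ≤ n_perm.
6. **Climate-covariate admixture.** A spatially explicit Bayesian
   admixture model with environmental covariates, fitted by MCMC, selected
   over a ladder of K by DIC, projected under future covariates, and
   summarized by ancestry-matrix correlation and per-cluster turnover.
7. **Genetic landscapes.** Pairwise genetic distances placed at spherical
   midpoints, interpolated by k-nearest-neighbour IDW (power 2, 12
   neighbours), clipped to the convex hull of the samples, and regressed on
   the signed suitability change (future − current) with a penalized cubic
   spline GAM.

## The admixture model

No published specification exists for the internals of the GUI tools this
model class is usually run in, so `clgc` defines its own fully specified
stand-in and documents it as such. It is a logistic-normal ancestry
regression: for individual *i* and cluster *k* < K,

z_ik = β_k · x_i + γ_k · s_i + ε_ik,  ε_ik ~ N(0, σ²),  z_iK = 0,

with x_i the standardized climate covariates, s_i the standardized
coordinates (degree-1 spatial trend), and ancestry Q_i = softmax(z_i). Gene
copies are assigned to clusters by data augmentation (Gibbs; probability ∝
Q_ik f_kla for allele a at locus l), cluster allele/haplotype frequencies
are Dirichlet-conjugate, (β, γ) have a normal conjugate update given z, σ²
is inverse-gamma, and z itself moves by an adaptive random-walk Metropolis
step tuned toward 0.25 acceptance during burn-in. The deviance is the
observed-data multinomial deviance −2 Σ log(Σ_k Q_ik f_kla); DIC uses the
Spiegelhalter p_D form (mean deviance minus deviance at posterior means).
Label switching is resolved by aligning clusters to a reference matrix with
an exact assignment search for K ≤ 7 and a greedy one above.

Projection under a future climate replaces x_i and keeps everything else:
Q′ = softmax(β̂x′ + γ̂s). With unchanged covariates this reproduces the
fit's regression-component ancestry exactly, which the tests assert; the
full posterior-mean Q additionally carries the individual noise ε and is
what diversity summaries use.

Headline runs use 20,000 sweeps after 2,000 burn-in over K = 2…20 with four
replicate chains (the `paper` profile); the synthetic fixtures in the tests
recover K_true = 3 structure from 150 individuals × 8 loci comfortably with
2,000 sweeps, which keeps the whole suite inside a half-hour budget.

## What the synthetic generator emulates — and what it does not

All tests run on data from `syntheticScenario()`, whose defaults encode the
study design the pipeline targets: 19 climate layers as smoothed Gaussian
random fields (FFT spectral synthesis, exact stationarity, seedable), 24
populations of ~9 individuals, 8 microsatellite loci with six possible
alleles each, 7 chloroplast haplotypes on a 1,000-bp alignment with one
diagnostic substitution per haplotype (so π and h are hand-computable), and
cluster ancestry driven by the leading three climate covariates through a
softmax regression.

Choices worth knowing:

* **Occurrence effect size.** Pipeline occurrences default to a steep
  logistic response (intercept −3, slopes −5 and +4 on the two leading
  layers), i.e. a species with a well-defined climatic envelope occupying a
  minority of the landscape. Weaker responses leave class overlap that caps
  achievable AUC near 0.65 and would make the 0.6 TSS/AUC gate reject
  everything — not a defect of the ensemble but of the data-generating
  signal. The orientation (negative on the warming axis) makes the uniform
  positive future trend erode suitability, emulating a warm-edge species
  that contracts under warming.
* **Future climate** adds a per-variable trend (+0.8 sd by default) plus
  small-scale noise (sd 0.1) to the current fields.
* **Isolation by resistance** (`ibr = TRUE`) draws per-population
  allele-frequency drift on the logit scale from a multivariate normal
  whose covariance decays exponentially in least-cost resistance distance
  (range = median pairwise resistance, sd 1.5). This yields median pairwise
  θ around 0.2–0.3 and a reliably positive, significant Mantel signal at 15
  populations — the magnitude a moderately differentiated outcrossing tree
  shows.
* **Not emulated:** coalescent genealogies, stepwise SSR mutation,
  recombination, sampling error in occurrence georeferencing, and
  observation bias. Passing tests therefore demonstrate that the estimators
  and the pipeline plumbing are correct and well-calibrated on data meeting
  their assumptions, not that any particular real dataset meets them.

## Numerical choices and degenerate inputs

* Correlation pruning is greedy: repeatedly drop the layer with the highest
  mean |r| among offending pairs, ties broken by layer name.
* Rarefaction is greedy first-come retention in input order, deterministic.
* Binarization is closed at the threshold (`≥`), so LPT keeps presences;
  "above the LPT" in persistence projection is read the same way.
* Friction's ε = 0.001 floor avoids zero-cost cycles on perfect habitat.
* Population coordinates snap to the nearest unmasked cell centre; the snap
  distance is recorded on the network nodes.
* Mantel tests permute the second matrix (B), not A; the one-tailed
  positive alternative is the isolation-by-resistance convention, with a
  two-tailed option. A conditioning matrix that is constant after centering
  reduces the partial test to the simple one; a predictor matrix perfectly
  collinear with the conditioning matrix is an error; a residual with no
  variance left (A = C) gives a partial r of 0 by definition.
* IDW uses the planar degree metric of the interpolation tools it mirrors;
  a cell coinciding with a sample takes the sample value exactly; a
  degenerate (< 3 point) hull is buffered by one cell.
* Negative Weir–Cockerham estimates are floored at 0 before linearization;
  F = 1 linearizes to Inf with a warning. Monomorphic loci contribute
  nothing to the ratio of sums (their variance components are all zero).
* π treats gaps/N as missing pairwise; haplotype identity treats gaps as
  significant (an indel is a real variant).
* The seed splitter gives stage *i* of a run with global seed *s* the seed
  `s + 1009·i`, so any stage can be re-run from cached upstream artifacts
  bit-identically.

## Problem sizes used by the test suite

The suite exercises everything on deliberately small instances: 20×20 to
40×40 grids, 8–25 populations, 150–216 individuals, 200–2,000 MCMC sweeps,
199–999 permutations. These sizes were chosen so each recovery check has
comfortable statistical headroom (e.g. ancestry recovery correlation ≥ 0.9
is met at ≈ 0.98) while the whole suite runs in well under a minute of the
budgets typical for continuous testing. The `paper` profile in
`defaultPipelineConfig()` records the full-scale defaults (9,999
permutations, 20,000/2,000 sweeps, K 2–20 ×4 runs, 1-km IDW cells) for
real-data runs.

## Known limitations

* The admixture stand-in has no CAR/Gaussian-process spatial prior and no
  tessellation-based interaction; its spatial term is a degree-1 trend.
  DIC values are therefore not comparable with other software's.
* Resistance is least-cost only; circuit-theoretic (all-paths) resistance
  is out of scope.
* The ensemble roster omits MARS and MaxEnt variants; the roster is
  configurable and the gating/ensembling contract is independent of it.
* Areas use the spherical cos(latitude) approximation, adequate at the
  cell sizes involved (relative error < 0.5%).
* ESRI ASCII grid is the raster interchange format; there is no GeoTIFF
  writer.

## A worked miniature run

```{r, eval = FALSE}
cfg <- defaultPipelineConfig("test", seed = 5)
state <- runPipeline(cfg)
state$range_shift$percent_change
state$mantel$current[c("r", "p")]
dic(state$admixture_fit)
state$stability_gam$r_squared
```

Each product is also written as CSV/JSON/ASCII-grid into the run directory
(`state$outdir`) together with a manifest carrying the seed and a config
hash.
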