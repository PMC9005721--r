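# spatSDM

Bias-aware species distribution modelling (SDM) for presence-only records,
built for the situation every user of citizen-science occurrence data faces:
records cluster around where people live, not where the species does. The
package implements a complete, reproducible pipeline —

1. **Grid I/O** — ESRI ASCII rasters (bioclimatic variables BIO1–BIO19 plus
   soil properties) aligned into a stack, with per-point covariate
   extraction;
2. **Spatial thinning** — enforce a minimum nearest-neighbour distance
   between retained records (presets 4, 7 and 10 km, 100 random restarts of
   a greedy max-degree removal heuristic, keeping the restart that retains
   the most points);
3. **Pseudo-absence generation** — a combination of the *disk* strategy
   (uniform background points at least 25 km from every presence) and a
   latitude-filtered *random* strategy (points north of 64°, beyond the
   species' cold limit);
4. **Covariate selection** — Pearson correlation grouping at |r| ≥ 0.8
   followed by random-forest importance ranking (mean decrease in Gini
   impurity, MDG, and permutation mean decrease in out-of-bag accuracy,
   MDA), with correlated groups resolved by candidate-model comparison
   under spatial cross-validation;
5. **Spatial block cross-validation** — 100-km square blocks assigned to
   13 folds, repeated 20 times, scored by ROC-AUC
   (`AUC = (concordant + ½·tied) / (n₁·n₀)`, the Mann–Whitney statistic);
6. **Suitability projection** — a random forest fitted on all assembled
   data predicts occurrence probability per cell for the present stack and
   for substituted future climate stacks (soil layers carried over
   unchanged), summarised as report-band fractions (p < 0.25, p > 0.5),
   means and spatial block variability.

A first-class **synthetic world generator** (`make_synthetic_world()`)
builds environmental stacks with planted correlation structure, a known
logistic true-suitability surface `p(x) = logistic(β₀ + Σ βᵥ xᵥ)`, a
population-accessibility sampling-bias field, and a tundra-like northern
limit — so every stage of the pipeline can be validated against ground
truth without downloading a single raster.

## Worked example

```r
library(spatSDM)

world <- make_synthetic_world(seed = 1)     # 60 x 60 cells, 24 covariates
th    <- thin_points(world$presences, 7, iterations = 100, seed = 2)
tr    <- assemble_training_set(th$points,
           pa_config(n_total = length(th$retained), seed = 3), world$stack)
sel   <- select_features(tr$features, tr$occ$label, coords = tr$occ,
                         rf_params = list(ntree = 300),
                         n_permutations = 3, seed = 4)
folds <- make_folds(tr$occ, block_km = 100, k = 13, repeats = 5, seed = 5)
cv    <- cross_validate(tr$features[, sel$selected], tr$occ$label, folds,
                        rf_params = list(ntree = 300), seed = 5)
model <- fit_final_model(tr$features, tr$occ$label, sel$selected, seed = 6)
map   <- project_suitability(model, world$stack)
```

This prints (via the objects' `print` methods):

```
synthetic_world: 60 x 60 grid, 24 covariates, 2000 presences (seed 1)
  informative: BIO1, BIO8, SOC
thinning_result: 1887 retained at >= 7 km (100 iterations, seed 2)
feature_selection: 15 of 24 variables kept (|r| >= 0.8 grouping)
  selected: BIO1, SOC, BIO10, BIO8, BIO18, Silt, BIO14, BIO5, BIO7, CEC, ...
cv_report: AUC 0.948 +/- 0.016 over 65 defined folds (0 skipped)
suitability_map [present]: mean 0.448, max 1.000 over 3600 cells
```

2000 biased records thin to 1887 at 7 km; selection recovers all three
planted informative covariates (BIO1, BIO8, SOC) at the head of the list
while keeping at most one member of each correlated group; spatially
blocked CV estimates AUC 0.948; and the projected map correlates with the
hidden true surface at r = 0.72 despite the sampling bias
(`cor(as.vector(map$grid$values), as.vector(world$truth$values))`).

`run_pipeline()` wraps the same stages behind a single
`pipeline_config()` with one global seed and returns a seven-stage
manifest; `run_thinning_sweep()` reproduces the four-way comparison
(no thinning vs 4/7/10 km) used to choose a thinning distance.

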