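---
title: "Bias-aware habitat suitability modelling with spatSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware habitat suitability modelling with spatSDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spatSDM)
```

## The problem

Correlative species distribution models relate presence records to
environmental covariates and project the fitted relationship over a raster
to map habitat suitability. When the records come from citizen-science
portals, two artefacts dominate: there are no absence records at all, and
record density tracks human accessibility rather than the species'
prevalence. A model trained naively on such data learns the observers, not
the organism: it reproduces the clusters of observation and scores the
rest of the territory as unsuitable, and conventional random-split
cross-validation rewards it for doing so because test points sit next to
training points in space.

`spatSDM` packages the standard counter-measures into one tested pipeline:
spatial thinning of the presences, pseudo-absence construction that avoids
the immediate neighbourhood of presences, covariate selection that removes
redundant predictors, spatially blocked cross-validation, and probability
mapping with a random-forest classifier.

## The pipeline, stage by stage

### Spatial thinning

`thin_points()` removes records until no two survivors lie within a
minimum great-circle distance `d` of each other (haversine on a sphere of
radius 6371.0 km). Maximising the number of survivors is a maximum
independent set problem on the proximity graph, so the implementation uses
the standard randomised greedy heuristic: while any point has a neighbour
within `d`, delete one point drawn uniformly among those with the most
neighbours; repeat the whole procedure (default 100 restarts) and keep the
best restart, first-found on ties. On instances small enough for exhaustive
search (n ≤ 14) the best-of-100 heuristic attains the exact optimum in
well over 95% of random geometries — this is asserted in the test suite.
Preset distances 4, 7 and 10 km are exposed; retention is non-increasing
in distance under a fixed restart schedule.

`compare_thinnings()` runs the full downstream pipeline once per candidate
distance (plus the unthinned baseline) and tabulates CV AUC, band
fractions and the spatial variability of predictions. The variability
diagnostic — mean over 100-km blocks of the within-block standard
deviation of cell predictions — operationalises the visual criterion "does
the map vary over the territory or merely echo the sampling clusters?"; a
model that memorises clustered records produces flat, low-variability
surfaces away from the clusters. The distance maximising block variability
is *suggested*, not imposed; the choice of a thinning distance ultimately
trades information loss against bias reduction and the table exposes all
the ingredients.

### Pseudo-absences

With presence-only data, binary classification needs constructed
absences. `assemble_training_set()` combines two strategies, half/half by
default:

* **disk** (`generate_disk()`): points uniform over the unmasked domain,
  accepted only if at least 25 km (default, configurable) from every
  presence. Rejection sampling is capped at 1000 proposals per requested
  point; if the cap is reached the function raises an infeasibility error
  naming the radius — it never silently returns fewer points.
* **latitude-filtered random** (`generate_random_filtered()`): uniform
  points north of a cold-limit latitude (default 64°), where the species
  cannot persist for climatic reasons, so random points are safe absences.

Pseudo-absence count defaults to one per (thinned) presence. A 1:1 design
keeps the classifier's vote proportions interpretable and AUC unaffected
by class imbalance; the ratio, the disk radius and the latitude threshold
are all exposed in `pa_config()`. Two optional modes exist for
experimentation and are off by default: thinning the pseudo-absences at
the presence thinning distance, and weighting disk proposals by an
accessibility field so that absences carry the same sampling bias as
presences. The latter mirrors a remedy sometimes applied to citizen
science data; it is provided as a mode rather than a default because its
interaction with the disk constraint is design-specific.

### Covariate selection

`select_features()` implements a two-stage filter:

1. **Correlation grouping** (`correlation_groups()`): Pearson correlations
   over training rows; variables joined whenever |r| ≥ 0.8 (threshold
   configurable); connected components form groups of mutually redundant
   covariates. Zero-variance columns are excluded with a warning.
2. **Importance ranking** (`rf_importance()`): a random forest supplies
   MDG (per-tree average Gini-impurity decrease credited to each variable)
   and MDA (drop in out-of-bag majority-vote accuracy when the variable's
   column is permuted, averaged over `n_permutations` independent
   permutations, default 10). MDA of an uninformative variable fluctuates
   around zero and may be slightly negative.

Singleton variables are kept when they rank in the top half by MDG *or*
MDA. The keep-rule needed a concrete numeric form where common practice is
discretionary ("keep the important ones"); top-half-by-either-ranking is
deliberately permissive — dropping a genuinely informative covariate harms
a projection far more than carrying some noise — and every kept/dropped
decision lands in a machine-readable audit log (`write_audit_log()`), with
a manual override (`pipeline_config(selected_override = ...)`) as a
first-class escape hatch. Multi-member groups are resolved sequentially:
shortlist the members with the best MDG and the best MDA rank; if they
coincide, keep that member; otherwise fit one candidate model per
shortlist member (current kept set plus the candidate, other group members
excluded) and keep the one with the higher cross-validated AUC — under
spatial folds when coordinates are supplied, random folds otherwise. The
tiebreak CV is deliberately lighter (5 folds, 1 repeat, 200 trees) than
the main evaluation: it only needs to order two nested models, not
estimate generalisation precisely.

### Spatial block cross-validation

`make_folds()` tiles the points' bounding box with square blocks (default
edge 100 km) in a local equirectangular projection — x scaled by
cos(mid-latitude), block index by `floor` on half-open cells — and assigns
whole blocks to k = 13 folds uniformly at random, 20 independent repeats
by default. If an assignment leaves a fold empty, a block is moved from
the currently largest fold, preserving k-fold semantics on small domains.
All points of a block always share a fold; this is the property that makes
the evaluation honest in the presence of spatial autocorrelation, and it
is asserted on every assignment in the tests. `make_random_folds()`
provides the conventional per-point baseline; on spatially structured
data, blocked AUC is systematically at or below random-split AUC — the
optimism the blocking removes.

`roc_auc()` is the tie-aware Mann–Whitney form; folds whose test (or
training) set contains one class have no defined AUC and are recorded as
skipped, never imputed. The aggregate is the unweighted mean and SD over
defined repeat × fold cells.

### Final model and projection

`fit_final_model()` refits the forest on all assembled rows restricted to
the selected covariates; `project_suitability()` predicts every unmasked
cell (union NODATA mask across the model's variables) and preserves NODATA
elsewhere. Future climate stacks are opaque named inputs; soil layers,
which change on much slower timescales than climate, are carried over
unchanged from the present stack by `carry_over_soil()`. `summarize_map()`
reports the fractions of cells below 0.25 and above 0.5 (the conventional
reporting bands for "likely unsuitable" and "likely suitable"), the mean
and maximum, and the block-variability diagnostic computed on cell centres
(deterministic and resolution-consistent; the bands partition the cells
exactly, which the tests assert to 1e-12). `compare_scenarios()` adds
cellwise difference maps against the first (present) map.

## Random-forest settings

Defaults, exposed everywhere via `rf_params`: 500 trees, `sqrt(p)`
candidate variables per split, no depth cap, and a minimum terminal-node
size of 25. The forests are used as *probability machines* — the class-vote
proportion is read as an occurrence probability — and fully grown trees
give high-variance, partially memorised vote proportions (a tree that
contains a training point in-bag votes that point's label for its whole
leaf). Terminal nodes of ~1% of a typical training set smooth the
probability surface considerably while leaving ranking metrics (AUC)
essentially unchanged. Scores for AUC are always probability votes, never
hard classifications.

## The synthetic study system

`make_synthetic_world()` generates the complete testbed and is itself part
of the package contract:

* **Domain**: 30° × 30° (lon 30–60 E, lat 40–70 N) at 0.5° cells — a
  60 × 60 toy of a large north-temperate study region, small enough that
  every stage runs in seconds.
* **Covariates**: 19 bioclim-like plus 5 soil-like fields; each is
  Gaussian-blurred white noise (blur 2 cells) standardised to mean 0,
  sd 1 — spatially autocorrelated but mutually independent unless planted
  otherwise. Planted correlation: BIO11 is rebuilt from BIO1 (and BIO16
  from BIO12) with noise scaled for r ≈ 0.92, always ≥ 0.85 empirically.
  BIO1/BIO11 additionally carry a negative latitudinal gradient, because
  annual-mean-temperature-like variables are strongly latitude-determined
  at continental scale; this also makes the northern cold limit partially
  learnable from covariates rather than pure label noise.
* **Truth**: `p = logistic(-0.5 + 2·BIO1 + 1.5·BIO8 + 1.5·SOC)` — two
  climatic and one soil driver, a strongly climate-limited niche with a
  saturated core and sharp margins. North of 64° a smooth logit penalty
  (−8 over a 2° ramp) forces suitability towards zero, emulating a hard
  tundra limit that motivates the pseudo-absence latitude filter.
* **Sampling bias**: accessibility is a sum of exponential kernels around
  30 population centres drawn from the seed across the non-tundra domain,
  with a 100 km decay — the halo of roads and regional recording effort
  around towns. Presences are drawn per cell with probability
  proportional to truth × accessibility and jittered within the cell
  (real records are not cell-centred, which exercises extraction).
  The bias is recoverable from the sample: presence density divided by
  truth correlates with the accessibility field.
* **Futures**: `make_future_stack()` shifts temperature-like variables by
  a constant (optionally within a latitude band); there is no climate
  model physics here, future stacks are perturbed inputs by construction.

What the generator does **not** emulate: interactions or non-monotone
responses in the truth, observer-specific detection probabilities,
coordinate error, temporal trends, or the shared large-scale structure
that makes real bioclim variables correlate in dozens of pairs rather
than the planted few. Passing tests therefore demonstrate that the
machinery mitigates accessibility-driven sampling bias under a known
monotone niche — not that any particular real-world map is correct.

## Numerical and degenerate-input policy

* ESRI ASCII headers are parsed case-insensitively; NODATA comparison is
  exact equality to the parsed sentinel; values are written with 8
  significant digits (round trips are lossless at 1e-6 relative, asserted
  in tests). Stacking requires exact header equality — no resampling is
  implemented, inputs must be pre-unified to one grid.
* Cell containment is half-open, closed on west and north edges; row 0 is
  the northern edge. A point invalid for one variable is invalid for all
  (single shared validity decision via the union mask).
* Distances use exact haversine with Earth radius fixed at 6371.0 km;
  block tilings use the equirectangular approximation only for block
  membership, never for distances.
* Thinning ties (equal neighbour counts) break uniformly at random within
  the seeded restart schedule; best-restart ties keep the first.
* Empty inputs: thinning an empty set returns an empty result; a
  single-class label vector is an error for any classifier fit;
  a fully masked map has no defined summary and errors.
* All stochastic stages take explicit integer seeds; `run_pipeline()`
  derives per-stage seeds from one global seed, and identical
  configurations reproduce identical manifests (hash-verified in tests).

## Problem sizes used by the tests and the acceptance script

The default study conditions (2000 presences, 60 × 60 grid, 24 covariates,
1:1 pseudo-absences, 25 km disk, 64° filter, |r| ≥ 0.8, 100-km blocks)
are kept throughout. Multi-seed experiments scale the per-fit knobs that
do not alter the conditions: thinning uses 10 restarts instead of 100
inside repeated experiments (retention differs negligibly), importance
forests use 300 trees and 3 permutations, cross-validation inside the
acceptance script uses 5 of the default 20 repeats. The interface exposes
all of these; nothing in the package depends on the reduced values.

## Limitations

* The pipeline assumes the covariate stacks are already aligned on one
  grid; there is no reprojection, resampling or GeoTIFF/NetCDF ingestion.
* Pseudo-absences are a design construct, not observations; with extreme
  sampling bias the disk strategy places absences in unvisited but
  suitable territory, and no evaluation on the biased sample can fully
  detect the resulting error — this is precisely what the synthetic truth
  experiments quantify.
* The block-variability map diagnostic is one operationalisation of
  "informative map structure"; it flags flat, memorised surfaces but is
  not a substitute for inspecting the maps.
* Future-scenario projections inherit every assumption of the fitted
  model; covariate combinations outside the training range are
  extrapolated by the forest's nearest leaves.
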