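---
title: "Inspecting learned embeddings for batch effects and bias"
author: "featurelens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inspecting learned embeddings for batch effects and bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featurelens)
```

## The problem

Encoders trained on whole-slide-image (WSI) tiles emit an embedding — a
vector of roughly 1000–1536 floating-point features — per tile. Those
embeddings should carry biology. In practice they often also carry the
tissue source site (TSS): stain chemistry, scanner characteristics and
slide preparation differ between institutions, and a model can exploit
these shortcuts instead of (or alongside) biology. Because outcome and
case mix also differ between institutions, a site-readable embedding is a
bias and overfitting hazard for every downstream model built on it.

`featurelens` inspects embeddings directly, so it is agnostic to the model
that produced them. Two complementary views are provided:

* a **linear probe** — a single affine layer trained on the frozen
  embeddings to predict a sensitive variable. Its held-out accuracy
  measures how *linearly decodable* the variable is; chance-level accuracy
  is the desired outcome for a variable like TSS.
* **2-D projections** with quantitative structure scores — silhouette and
  a k-means/adjusted-Rand comparison measure how strongly the sensitive
  variable separates in the plane, while k-nearest-neighbour preservation
  and the Spearman correlation of pairwise distances (CPD) measure how
  faithful the plane is to the original geometry, i.e. how much the
  picture can be trusted.

Everything operates on one container, the `EmbeddingSet`: an n × d feature
matrix with item ids and aligned categorical metadata (site, stage,
patient, slide, ...), implemented on top of `SummarizedExperiment`.

## The linear probe

The probe is the map `softmax(W'x + b)` from d standardised features to m
class probabilities, trained by mini-batch Adam on the softmax
cross-entropy for exactly `epochs` passes. Defaults: 20 epochs, batches of
256, learning rate 1e-3, beta1 0.9, beta2 0.999. Features are
standardised per dimension with statistics from the training split only;
the standardisation travels with the model so evaluation cannot leak test
statistics. At predict time the softmax is omitted (it is monotone) and
ties in the argmax resolve to the lowest class index; class order is
lexicographic. Both choices exist for determinism: given the same data
and seed, training reproduces bitwise-identical weights, because the
weight initialisation and every epoch's shuffling order are drawn from a
single seeded stream.

Uncertainty is quantified on the held-out set by the percentile bootstrap:
the test set is resampled with replacement `nBootstrap` (default 100)
times, and the 2.5/97.5 percentiles of the resampled accuracies form the
95% interval. Cohen's kappa,

$$\kappa = \frac{p_o - p_e}{1 - p_e},$$

with observed agreement `p_o` and chance agreement `p_e` from the
confusion matrix, is computed *per bootstrap replicate from that
replicate's confusion matrix* and averaged. Averaging per-replicate
kappas, rather than deriving kappa from the accuracy, is deliberate:
kappa is not a function of accuracy alone, and replicate-level confusion
matrices keep the chance correction honest under class imbalance. When a
replicate's chance agreement is exactly 1 (a single occupied cell) its
kappa is undefined and excluded; if every replicate is undefined the
reported kappa is `NA`.

`subsampleExperiment()` re-runs the probe on stratified subsamples of the
training data at given fractions, keeping the test set fixed. At
fractions of 25% or less the epoch count is raised to 60 by default,
compensating for the reduced number of optimiser steps; both the
threshold and the raised count are arguments.

## Projections

`projectEmbeddings()` exposes one contract with two methods. The
`neighbor_embedding` method delegates to whatever reducer has been
registered with `setReducer()` — typically a UMAP binding — passing
`nNeighbors` (default 15), `minDist` (default 0.1) and the seed through
unchanged. The package deliberately does not re-implement the
neighbour-embedding optimisation; the reducer is a runtime plug-in so the
heavy dependency stays optional.

The built-in `linear_fallback` centres the features and projects onto the
top two principal directions, computed by an iterated power method with
deflation (tolerance 1e-10 on the normalised step, at most 1000
iterations), with each direction's sign fixed so its largest-magnitude
loading is positive. It is fully deterministic, permutation-equivariant
(the start vectors depend only on the seed, never on row order), and
makes every score and report testable without a neighbour-embedding
backend. Degenerate inputs are handled explicitly: rank-1 data yields an
exactly-zero second coordinate because the second component is scored
against the deflated matrix.

There is no universally optimal `(nNeighbors, minDist)` for bias
detection, and the package does not pretend to know one: `projectGrid()`
sweeps the Cartesian grid of both parameters from one identical input
sample, and the HTML report lays the panels out for side-by-side
comparison. Similarly, patterns depend on sample size — small samples
expose local structure, large ones global structure — so
`drawProjectionSample()` supports repeated sampling at several sizes
(defaults 10000 and 70000), optionally stratified by a variable with
largest-remainder rounding.

## Structure scores

Four scores are bundled by `scoreProjection()`:

* **Silhouette**: mean over points of `(b − a) / max(a, b)` where `a` is
  the mean distance to same-label points and `b` the smallest mean
  distance to another label; singleton labels score 0.
* **k-means ARI**: Lloyd's algorithm with k = number of labels, greedy
  farthest-first initialisation from a seeded start, 10 restarts (best
  within-cluster sum of squares wins), at most 300 iterations or centroid
  shift below 1e-4; the resulting partition is compared to the labels by
  the pair-counting adjusted Rand index.
* **KNN preservation**: mean fraction of each point's k nearest
  neighbours (Euclidean, self excluded, ties broken by lower index)
  shared between the high- and low-dimensional spaces. Default k = 15,
  matching the projector's neighbourhood default so the metric measures
  the neighbourhood size the projection optimised.
* **CPD**: Spearman correlation (average ranks) between the vectors of
  all pairwise distances in both spaces.

Pairwise-distance costs grow quadratically, so CPD caps its input at 1000
points (≈ 500k pairs) and `scoreProjection()` caps the whole scoring at
5000 points, both via seeded uniform subsamples recorded in the result.

A documented caveat: when a label's items form several internally-distant
clusters in the plane (five hospitals each split into two stain batches,
say), silhouette and ARI are pulled toward zero even though the grouping
is visibly there. The scores are reported as defined; no correction is
attempted. KNN/CPD are unaffected because they never look at labels.

## Data curation

The curation operations mirror how a tiled WSI cohort is prepared:

* `tileGrid()` tessellates a slide into `tileSide`² tiles (default 1024)
  with fractional overlap (default 0.25, stride 768); partial edge tiles
  are dropped rather than padded, since downstream encoders need
  fixed-size inputs.
* `whitespaceFraction()` counts pixels whose three channels all reach 220
  on the 8-bit scale — the package's operational definition of scanned
  background, configurable. `filterWhitespace()` removes tiles *strictly
  above* 85% whitespace; a tile at exactly the threshold is kept.
* `topNGroups()` ranks groups by item count (ties by id) to restrict an
  analysis to the largest sites, which keeps samples per class sufficient
  for probing and projection.
* `balanceByCovariate()` first drops covariate levels absent from any
  group — the generalisation of excluding a tumour stage only one site
  has — then subsamples every (group × covariate) cell to the global
  minimum cell count. Exact min-cell equalisation is the strongest
  testable reading of "comparable distributions": after it, covariate
  composition cannot confound a group comparison. The cost is discarding
  data down to the smallest cell; the operation is tile-level.
* `patientDisjointSplit()` shuffles units (patients by default) with the
  seed and assigns each greedily to the split with the largest current
  item shortfall against its target (0.70/0.15/0.15 by default). All of a
  unit's items follow it, so splits are leakage-free by construction, and
  per-split proportions deviate from targets by at most the largest
  unit's share.

## The synthetic generator

`genEmbeddings()` provides the controlled conditions every other module is
validated against. Each item's feature vector is

$$x = s\,\mu_c + \delta\,v_s + \sigma\,\varepsilon,$$

with fixed orthonormal class directions μ (the first `nClasses` basis
vectors), site directions v (the next `nSites`), class separation `s`,
batch-effect magnitude δ, and i.i.d. standard normal noise ε. Orthonormal
rather than random directions are chosen so the geometry is analytic:
site centroids sit at pairwise distance δ√2, δ/σ is a true signal-to-noise
ratio, and class/site signals are exactly orthogonal — so balancing
classes provably cannot change expected site separability, which the test
suite exploits. Defaults emulate a five-site, three-stage cohort with a
patient/slide hierarchy (`nSites` 5, `nClasses` 3, d 64; d = 1536 matches
a realistic encoder width when wanted). Stages are assigned at patient
level from a balanced, seed-shuffled label vector: the marginal is
uniform and every class is guaranteed occupied, which the balancing and
probing operations need.

What the generator does **not** emulate: stain and scanner texture,
within-site heterogeneity, non-Gaussian or correlated noise, class/site
signal overlap, or tile-to-tile correlation within a slide beyond shared
means. Passing tests therefore demonstrate that the machinery measures
what it claims under known conditions — not that any particular real
cohort is or is not biased.

`genTiles()` builds toy image tiles with an exact number of white pixels,
so the whitespace filter can be checked against ground truth by
construction.

## Training-loop hooks

`onEpochEnd(epoch, embeddings, policy, history)` is the whole integration
contract: the host loop hands over its validation embeddings, nothing
else. On epochs divisible by `everyN` (default 20) the hook splits the
embeddings by the policy's unit variable with the greedy 70/15/15
splitter, trains on the train portion, evaluates on the remaining 30%,
appends one record per variable, optionally projects and scores, and
returns `stop` when the configured accuracy threshold is crossed. The
in-loop probe config is lighter — 5 epochs, 25 bootstrap resamples, and
batches of 32. The smaller batch is step-count arithmetic: a validation
set of a few thousand items at batch 256 would give the optimiser only a
handful of updates per epoch within the 5-epoch budget, far too few to
fit even a trivially separable probe; batch 32 restores roughly a
hundred updates on a 2500-item validation set, enough for the probe to
reach its asymptotic accuracy on strongly separable data. Histories are
written as JSON lines (`writeHistory()`), one record per line,
append-safe across restarts.

## File formats and the report

The text dialect is a delimited table with one `id` column, `meta_`-
prefixed metadata columns, and `f0…f(d−1)` feature columns; features are
printed with 17 significant digits so text round-trips are exact for
doubles and a save→load→save cycle is byte-stable. The binary dialect is
a single Arrow/Feather columnar file holding the same columns with
float64 features; float64 rather than a narrower type is deliberate, as
the binary dialect guarantees `load(save(x)) == x` exactly and R's native
numeric is 64-bit. Raw tile pixels enter the embedding world via
`pixelsAsEmbeddings()`: area-average (box filter) resize — deterministic
and exactly checkable against hand-computed block means — then row-major
flattening of the three channel planes, scaled to [0, 1].

`buildReport()` writes one self-contained HTML file: all projections as
zoomable scatter panels on the parameter grid, a colouring-variable
selector, per-class show/hide toggles, raw-pixel companion panels side by
side when present, and the score table. All data are embedded as JSON
inside the document and no external resource is referenced, so the file
can be shared as-is. `exportScoresTable()` writes the same numbers as TSV
for consoles and pipelines.

## Validation conditions and limitations

The package validates itself on the synthetic generator at desk scale:
probe recovery uses 5000 tiles (5 sites × 25 patients × 2 slides × 20
tiles, δ/σ = 10) for the strong-signal case and 6800 tiles for the
chance-level case (held-out portion above 2000 items); the
monotonicity-in-δ and subsample-trend properties use 1500- and 3000-tile
cohorts over five seeds. These sizes were chosen as the smallest at which
the respective statistics are stable; all are arguments, not constants.

Known limitations: the probe detects only *linearly* decodable signal — a
chance-level probe does not certify the absence of nonlinearly encoded
bias; silhouette/ARI share the multi-cluster caveat above; the linear
fallback shows global variance structure, not the local manifold detail a
neighbour embedding reveals; and min-cell balancing can discard most of a
cohort when cells are very uneven.
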