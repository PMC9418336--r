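---
title: "Mapping active cropland and short-term fallows: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping active cropland and short-term fallows: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallfield)
```

## The problem

Smallholder landscapes in Sub-Saharan Africa are hard to map from satellite
imagery: fields are mostly smaller than 0.64 ha, management is heterogeneous,
land rotates rapidly between active cultivation and short-term fallow, and
cloud cover erodes the usable observation density. `smallfield` implements a
complete mapping pipeline for this setting, built around monthly 4-band
mosaics at a nominal 4.77 m pixel: multi-temporal coregistration, a
time-series consistency statistic, seasonal/texture/contrast features,
margin-driven active learning around a random-forest classifier, and
design-based accuracy assessment with unbiased area estimation. Every stage
runs on seeded synthetic scenes, so the whole chain is testable without any
satellite data access.

The seven-class scheme separates *active cropland* (signs of recent
management) from *short-term fallow* (cultivated within the last ~5 years),
plus herbaceous vegetation, open/closed woodland, unvegetated surfaces and
water (`class_catalog()`).

## Coregistration

Monthly mosaics carry multi-temporal misregistration: the same field edge
lands on different pixels in different months. Each month's NIR band is
matched against the median NIR composite of its 4-month season
(September-December, January-April, May-August); compositing damps both
phenology and jitter, and an external well-registered composite can be
supplied instead where available (`coregister_series(reference = ...)`),
which is the preferred mode and mirrors operational practice of matching
against an independent reference sensor.

The estimator is multi-scale block cross-correlation ("rubber-sheeting"):

* a global integer shift from normalised cross-correlation at the coarsest
  pyramid level, refined level by level (`levels`, default 3);
* per-block (default 64 px) search in a small radius around the propagated
  shift, with quadratic sub-pixel refinement of the correlation peak;
* blocks whose peak correlation falls below 0.3 are treated as
  uninformative (textureless water, cloud) and inherit the smoothed
  neighbourhood estimate;
* Gaussian smoothing of the block field with sigma = `stiffness`/2 block
  units. The platform parameter the published workflow used is opaque; we
  promise only a monotone equivalence — higher stiffness, smoother field —
  and expose the mapping in `coreg_config()`;
* offsets clamped to `max_offset_m` (default 100 m), and tiled processing
  with a buffer of at least the maximum offset so clamped offsets never
  read outside a buffered tile.

Known limitation: smoothly varying (non-rigid) displacement is recovered at
block resolution only; on synthetic scenes with smooth 3 px warps the
residual is ~0.8 px, while constant shifts up to 15 px are recovered below
0.2 px. Terrain-dependent distortion is out of scope.

## Time-series noise

Residual misregistration shows up as month-to-month flicker in NDVI. The
noise statistic is the mean squared deviation of each interior observation
from the linear interpolation of its temporal neighbours:

$$TSNoise = \frac{1}{N-2}\sum_{i=1}^{N-2}\Big(y_{i+1} - \big[y_i +
(y_{i+2}-y_i)\tfrac{m_{i+1}-m_i}{m_{i+2}-m_i}\big]\Big)^2$$

with $y_i$ the NDVI observations and $m_i$ their month indices. Masked
months shrink the triplet set rather than being imputed; unequal spacing
enters through the month terms. The printed form of this statistic in the
source literature is typographically ambiguous; we implement the reading
consistent with its prose definition (deviation of the centre value from
the chord of its triplet), and expose a square-root variant (`root = TRUE`)
since the units of published density figures are not recoverable. The
statistic is non-negative, zero iff interior points lie on their chords,
invariant to additive shifts, and scales as $a^2$ — all tested exactly.
High values need not mean misregistration: genuinely dynamic surfaces
(floodplains, multiple cropping cycles) are also flagged.

## Features

Per season window: P50 of green, red, NIR and NDVI plus P75 of NDVI (15
layers; percentiles use linear interpolation between order statistics,
quantile type 7 — the source is silent, so the convention is fixed and
documented). Texture indices are focal medians of the seasonal NDVI P50 in
circular kernels of 25/100/200 m radius (pixel centres within the radius,
truncated at edges) for the first and third season; contrast indices
normalise each pixel against its kernel median,
$CI = (P50 - TI)/(P50 + TI)$, with 0 at zero denominators. Elevation,
slope (central differences, degrees), latitude and longitude complete the
default 31-layer stack; the layer order is fixed and recorded in a JSON
manifest. Feature extraction at points reads the containing pixel without
interpolation.

## Classifier and active learning

The classifier is a random forest (250 trees by default, Gini splits,
per-split `sqrt(p)` feature sampling, probabilities by averaging leaf
distributions). No random-forest implementation exists among the package's
allowed dependencies, so a compact deterministic one is implemented in C++
(`src/forest.cpp`); any calibrated probabilistic multiclass learner would
satisfy the surrounding contracts.

Active learning mirrors the two-stage published workflow: an initial
random per-class sample; per-pixel probability margins
$M_{prob} = p_{(1)} - p_{(2)}$; class-wise 25th-percentile margin
thresholds (computed exactly on small rasters, on a seeded subsample of at
most $10^6$ pixels on large ones — whether the original workflow used all
pixels is unstated, so the subsampling is documented as a deviation);
50 locations per class sampled below the threshold; labels from a pluggable
callback (synthetic truth in tests, human-in-the-loop files in production);
retraining. A targeted single-class pass (`target_classes`) reproduces the
fallow-specific augmentation pattern for rare, hard-to-train classes.
Argmax ties break toward the lowest class code for deterministic maps.

## Validation and area estimation

The stratified design follows standard good-practice estimation. Sample
size $n = (\sum_i W_i \sqrt{UA_i(1-UA_i)}/SE)^2$; with $UA_i = 0.75$ and a
1% target standard error this gives $n = 1875$ regardless of weights, and
allocation assigns a 200-per-class floor with the remainder (475)
distributed by largest-remainder rounding. From stratified counts the
estimators are $p_{ij} = W_i n_{ij}/n_{i\cdot}$, $OA = \sum_j p_{jj}$,
$UA_i = p_{ii}/p_{i\cdot}$, $PA_j = p_{jj}/p_{\cdot j}$, error-adjusted
areas $\hat A_j = p_{\cdot j}$, with the standard design-based variances
and 1.96-SE intervals. Producer's-accuracy and merged-class variances use
Taylor linearisation per original stratum, which reduces to the textbook
formulas when each class is one stratum, so class merging (e.g. to
active/fallow/non-cropland) keeps design-based CIs. Unlabelable units are
excluded with design weights unchanged (treating them as a stratum is a
noted alternative, not the default).

Published probability-populated matrices are ingested as printed: cell sums
may deviate from 1 by up to $10^{-3}$ and renormalisation is opt-in, so the
reproduced figures match the publication; ratios of rounded cells can
differ from printed accuracies by up to ~0.2-0.3 percentage points (e.g.
the merged water row). CIs require counts and are absent in proportions
mode.

## Aggregation

`gridcell_fractions()` reports exact pixel-count shares of active cropland,
fallow and total cropland per grid cell (partial edge cells keep their true
pixel counts, so totals are conserved), and `fallow_share_curve()` bins the
fallow fraction of cropland against the cropland share. The accessibility
covariate of the original analysis is an external dataset and out of scope;
the curve accepts any per-cell covariate column the user joins. The
map-based fallow share is reported alongside the design-based estimate
(`fallow_share_comparison()`); under fallow omission bias the map-based
share is the smaller one, the documented underestimation pattern.

## The synthetic world

The generator states one fixed world rather than a tuning surface:

* **Class mixture** defaults to the published error-adjusted area shares
  (active 16.2%, fallow 6.6%, herbaceous 11.2%, open woodland 39.1%,
  closed woodland 24.0%, unvegetated 2.1%, water 0.7%).
* **Patches** by capacity-constrained Eden growth from jittered-grid seeds;
  field classes use ~280-pixel patches (0.64 ha at 4.77 m), woodland
  patches are larger. Realised shares match the request to rounding.
* **Phenology**: no quantitative trajectories are published, so the
  12-month NDVI curves are free parameters chosen to encode the stated
  seasonality (cropland green-up/harvest cycle, damped fallow version,
  ever-green woodland); reflectance is derived so NDVI reproduces the
  trajectory exactly, making the noiseless render an exact oracle.
* **Noise**: independent per-band Gaussian noise (default sd 0.02) plus a
  static low-frequency NDVI perturbation field (default sd 0.05) that
  shifts whole regions greener or drier. The latter matters: it makes
  class ambiguity spatially coherent, the way real moisture/condition
  gradients do. With purely i.i.d. pixel noise, low-margin pixels are just
  extreme noise draws and margin-targeted sampling harvests unrepresentative
  points — a misleading world for testing active learning.
* **Misregistration**: per-month smooth low-frequency fields plus optional
  constant shifts. Mosaic misregistration is translation-dominant at tile
  scale, so the coregistration benefit tests use constant monthly shifts
  (up to 3 px) with a small smooth component.
* **Clouds** as random elliptical blobs recorded in the validity mask only,
  since downstream compositing consumes masks, not perturbed radiances.

What a green test does *not* establish: radiative realism, real mosaicking
artifacts, topographic illumination, or the magnitude of the accuracy gain
of active learning on real imagery (the published +12 percentage points is
not desk-reproducible; the synthetic analogue asserts only that margin
sampling beats same-budget random augmentation in most seeded replicates,
with the margin batch sized like the published one at roughly 10-15% of the
final training set).

## Numerical conventions

Row 1 is the northern edge; pixel centres carry coordinates (origin +
half-pixel); displacement `(dx, dy)` points toward increasing column/row,
and applying a field samples the source at `(row + dy, col + dx)`, so the
estimated field maps a target back onto the reference geometry. Bands are
warped bilinearly, validity masks by nearest neighbour; pixels warped from
outside the grid become invalid. Percentiles are quantile type 7
throughout. Forest training and the margin quantile use seeded, documented
RNG streams; the C++ forest has its own generator so results do not depend
on R's RNG state. On-disk rasters are plain-text ASCII grids (one band per
file) because no binary-raster package is available in the supported
dependency set; real-data users will typically convert GeoTIFFs externally.

## Known limitations

* Block-resolution displacement recovery (see above); no orthorectification
  or terrain-dependent correction.
* The forest is compact rather than feature-rich (no class weights, no
  out-of-bag estimates); it is deliberately replaceable behind
  `train_classifier()`.
* Proportions-mode estimates carry no uncertainty; printed matrices cannot
  recover the counts that produced them.
* The demo pipeline labels validation samples from the synthetic truth;
  real use requires an interpretation workflow outside this package.
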