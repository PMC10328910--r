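---
title: "Methods: nuclear morphometry, CFLCM heterogeneity, and dual-horizon recurrence prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear morphometry, CFLCM heterogeneity, and dual-horizon recurrence prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoprog)
```

# The problem and the model

Clear cell renal cell carcinoma shows few architectural features; its
prognostic signal is concentrated in nuclear morphology and chromatin
texture — the same cues behind Fuhrman grading, measured here quantitatively
instead of by eye. The pipeline turns segmented nuclei into case-level
predictions of *whether* and *when* a tumor recurs after nephrectomy, in
four stages: per-nucleus features, ROI-level spatial aggregation, two
horizon-specific classifiers, and a quadrant combination of their
probabilities.

The modeling assumptions, made explicit:

* the prognostic signal lives in the distribution *and spatial arrangement*
  of nuclear shape/texture within a tumor region, not in any single nucleus;
* ROIs of one case are exchangeable samples of the tumor, so a case's
  recurrence probability can be estimated by averaging its ROI
  probabilities;
* timing information is separable into two binary horizons (recurrence by 5
  years; recurrence by 10 years) whose combination localizes the recurrence
  window.

# Per-nucleus features (80)

`extract_nucleus_table()` computes, per labeled nucleus:

* **20 size/shape descriptors** — area (pixel count), perimeter (weighted
  boundary-crack estimator with the standard 4-connectivity weight
  categories 1, √2 and (1+√2)/2), form factor 4πA/P², moment-based
  eccentricity, major/minor axis lengths and orientation, solidity and
  convex area from the pixel-center convex hull, extent, equivalent
  diameter, compactness (2π·E[d²]/A, equal to 1 for a disk), max/min Feret
  diameters (rotating-calipers on the hull), bounding-box height/width,
  Euler number (2×2 quad-count formula), centroid-to-boundary mean/max
  radius, and aspect ratio (minor/major).
* **52 texture features** — the 13 Haralick statistics of the symmetric,
  direction-pooled gray-level co-occurrence matrix at offset distances
  {1, 2, 4, 8}, with intensities quantized to 8 gray levels per nucleus by
  min–max scaling. Per-nucleus (not global) quantization makes texture
  invariant to affine intensity rescaling, i.e. robust to staining-intensity
  variation; a test asserts this invariance directly. The sum variance is
  centred on the sum average (the well-known correction to the original
  1973 formula set); entropies use natural logarithms.
* **8 radial features** — fraction of total intensity and
  pixel-share-normalized mean fraction over 4 equal-width concentric rings
  from the centroid to the farthest pixel.

The multiple published counts of the feature set (80 in the methods and
results of the motivating work, 90 once in its discussion, with the full
list in an unavailable supplement) mean the exact identity of the original
features cannot be copied; this manifest is a reconstruction that spans
every named family and totals exactly 80. It is serializable
(`write_manifest()`) and replaceable; all downstream counts scale with its
length.

Degenerate inputs are defined, not rejected: a single-pixel nucleus has
perimeter 0 (a property of the crack estimator) and form factor defined as
0; nuclei admitting no pixel pair at some offset get 0 for that distance's
13 texture features with a warning; a nucleus whose pixels are equidistant
from the centroid falls back to a single radial ring.

# CFLCM aggregation (960 per ROI)

The cell-feature-level co-occurrence matrix transfers Haralick's idea from
pixels to cells: each nucleus is treated as one "pixel" whose "gray level"
is its quantized feature value, and co-occurrence is counted over spatially
neighboring nuclei. Per base feature:

1. `quantize_feature()` bins the ROI's values into **8 equal-frequency
   levels** (per-ROI quantile binning, type-7 quantiles, left-open
   intervals; constant features collapse to level 1). Equal-frequency
   binning is scale-free, so no feature needs pre-standardization.
2. `build_neighbor_graph()` connects each nucleus to its **5 nearest
   centroids** (symmetrized: an edge exists if either end is among the
   other's k nearest; distance ties broken by nucleus index). The scattered
   centroids of real tissue have no canonical pixel offset; a literal
   rasterization of nuclei onto a grid is a plausible alternative reading of
   "treating each nucleus as one pixel", but the symmetrized k-NN graph is
   scale-free, parameter-light, and well defined at any density, so it is
   the package's interpretation. k = 5 approximates the typical contact
   number of planar point neighborhoods (Delaunay degree ≈ 6) while
   guaranteeing connectivity of isolated pairs.
3. `build_cflcm()` increments cells (level_i, level_j) and (level_j,
   level_i) per edge and normalizes — a symmetric matrix summing to 1. With
   no edges (single nucleus) the zero matrix is flagged degenerate and all
   statistics are 0.
4. `cflcm_statistics()` returns 10 standard co-occurrence statistics:
   contrast, dissimilarity, homogeneity, angular second moment, entropy,
   correlation, cluster shade, cluster prominence, maximum probability, and
   inverse difference moment. The motivating work confirms only "mean,
   standard deviation, and heterogeneity by CFLCM" as the per-feature
   statistics and fixes the total at 960 = 80 × 12; the identity of the 10
   CFLCM statistics is therefore a design choice made once, from the
   standard co-occurrence repertoire, and frozen. Correlation of a
   degenerate (zero-variance) marginal is defined as 0.

`aggregate_roi()` emits mean, SD (n−1 denominator) and the 10 CFLCM
statistics per base feature, feature-major, a frozen 960-column order. ROIs
with fewer than 5 nuclei are skipped with a logged reason: below that the
k-NN graph and the 8-level quantization both degenerate.

Two properties pin the construction down and are tested: the ROI vector is
invariant to row permutation of the nucleus table, and two ROIs with
identical per-nucleus feature *values* but different spatial arrangements
(clustered vs. interleaved phenotypes) agree exactly in every mean and SD
while differing in CFLCM contrast — the statistic measures arrangement, not
composition. On instances small enough to enumerate (≤ 20 nuclei, ≤ 200
pixels) the GLCM, the k-NN edge set, the CFLCM and the full 960-vector are
each checked against independent brute-force reimplementations.

# Cohort structure and the two horizons

`assign_group()` encodes the four-group timing scheme: A = recurrence ≤ 60
months; B = recurrence in (60, 120]; C = recurrence-free with 60–120 months
of follow-up; D = recurrence-free beyond 120 months. Recurrence-free cases
with under 60 months of follow-up are uninformative for a 5-year label and
are excluded. A recurrence *after* 120 months has no group under this
scheme; such cases are excluded with a warning rather than silently binned.

The 5-year model labels A positive and B/C/D negative. The 10-year model
labels A/B positive and D negative; group C cannot be labeled (follow-up
ended inside the 10-year window) and is carried through as prediction-only.
`split_cohort()` stratifies by group at a 3:1 train:test ratio, and accepts
exact per-group test counts (`n_test = c(A = 10, B = 4, C = 9, D = 8)`)
because a published bookkeeping need not equal `round(n/4)` for every group
(22 group-B cases give 5.5). The split is **by case**: every ROI of a case
stays on one side, preventing leakage between training and test.

# Classifier and probability aggregation

`train_horizon_model()` fits a linear-kernel SVM (`e1071`, the library the
motivating study used) on ROI vectors z-scored with training-set means and
SDs (an SD of 0 is replaced by 1). Linearity is a contract, not an
implementation detail: a test probes that the decision value is affine in
the input, and `tidy()` exposes the weight vector explicitly. Probabilities
come from the standard sigmoid-on-margin (Platt) calibration built into the
library. Cost stays at the library default of 1 and is recorded in the
model object; no class weighting is applied. Any tuning loop is the user's
explicit choice via the `cost` argument.

`predict_case()` averages a case's ROI probabilities — the exchangeability
assumption above — and calls recurrence iff p > 0.50 strictly: the cutoff
defines recurrence as *more than* 50%, so a tie sits on the non-recurrence
side. `combine_horizons()` maps (p5, p10) to Q1/Q2/Q3/Q4; the four
predicates partition the unit square exactly (tested on boundary points),
and Q4 — 5-year recurrence predicted but 10-year not — is a deliberate
"contradictory" category rather than an error.

# The synthetic generators

Real slides cannot ship with the package, so two seeded generators define
the test conditions.

**Image path** (`generate_roi_image()`): nuclei are axis-rotated ellipses
with lognormal area (parameterized by mean and CV), Beta-distributed
eccentricity (concentration 20 around the phenotype mean), and uniform
orientation, placed by rejection sampling (1000 attempts per nucleus, then
an explicit capacity error) with a one-pixel halo so components stay
unambiguous. Chromatin texture is smoothed multiplicative Gaussian noise:
the smoothing bandwidth shrinks as `texture_contrast_level` rises, so
stronger phenotypes are more finely patterned; background is constant.
Identical seeds give bit-identical images.

**Fast path** (`generate_nucleus_table()`, `generate_cohort()`): per-nucleus
features are drawn directly as unit-variance Gaussians with group-shifted
means, bypassing image rendering so classifier-level behaviour can be tested
at cohort scale. Two latent axes carry the outcome signal — an early-
recurrence axis (first half of the features) and a late-recurrence axis
(second half). Group A is shifted `effect_size` SD on both axes, group B on
the late axis only (so the A shift dominates, keeping the horizons
distinguishable), C and D sit at baseline. Within each ROI, half the nuclei
form a "variant" subpopulation with an extra shift whose spatial arrangement
interpolates from fully clustered (`mixing = 0`) to fully interleaved
(`mixing = 1`), giving the CFLCM statistics real structure to measure.
Follow-up months are uniform inside each group's defining window (A:
6–59 with recurrence; B: 61–119 with recurrence; C: 61–119 censored; D:
121–200 censored) — the windows are fixed by the group definitions, the
within-window distribution is a modeling choice. `effect_size = 1` is the
default study condition: at 100 nuclei per ROI a 1-SD per-nucleus shift is
an ROI-level separation of ~10 standard errors, i.e. "strong effect", while
`effect_size = 0` makes all groups exchangeable for null calibration.

What the generators deliberately do **not** emulate: H&E color and stain
variation, segmentation errors (merged/split nuclei), lymphocyte
infiltration, nucleolar substructure, or any real correlation structure
among the 80 features. Passing tests therefore demonstrate that the
pipeline's mechanics are correct and that it recovers planted signal of the
assumed form — not that real ccRCC cohorts are predictable at any particular
accuracy.

# Problem sizes, determinism, and numerical choices

The test suite runs the full study twice: once at study scale (131 cases =
40/22/37/32 across A–D, 10 ROIs/case, 100 nuclei/ROI, `effect_size = 1`)
where held-out A/B/D cases must land in Q1/Q2/Q3 with ≥ 90% agreement, and
once at reduced scale (66 cases, 5 ROIs/case, 50 nuclei/ROI) with
`effect_size = 0`, where quadrant agreement must collapse toward chance.
These sizes keep a complete run in a couple of minutes on one core while
leaving the ROI-level sample sizes (1310 and 330) large enough for stable
SVM behaviour.

All randomness flows through explicit integer seeds via `withr::with_seed`,
leaving the caller's RNG state untouched; identical specs give identical
cohorts bit for bit. Accuracies are displayed rounded half-up to one
decimal (the convention of the published result tables; `floor(10x + 0.5)/10`,
avoiding banker's rounding at .05 boundaries), with raw fractions available
via `digits = NULL`. Co-occurrence matrices are validated to sum to 1 within
1e-8 before statistics are computed.

# Known limitations

* The 80-feature manifest and the 10-statistic CFLCM set are faithful
  reconstructions of counts and families, not copies of an unavailable
  original list; feature-level comparisons with other implementations
  should go through the manifest names, not positions.
* The k-NN reading of cell-level co-occurrence is one of two defensible
  interpretations (the other being literal rasterization of centroids onto
  a coarse grid).
* Segmentation is out of scope: the pipeline consumes labeled masks and
  inherits whatever errors produced them.
* The synthetic cohort plants linear mean-shift signal, which a linear SVM
  is exactly suited to; real morphological signal need not be linear in
  these features.
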