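---
title: "Automated OSS grading of corneal fluorescein staining: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated OSS grading of corneal fluorescein staining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Corneal fluorescein staining (CFS) is a core biomarker of dry eye disease:
fluorescein pools in damaged epithelium and images as green dots and
patches under blue light. Clinically the inferior cornea is graded on the
Ocular Staining Score (OSS): base score 0 (no staining), 1 (1-5 dots),
2 (6-30 dots), 3 (more than 30 dots), plus one point each for patches of
confluent staining, corneal filaments, and staining in the central cornea,
capped at 5 for a single region of interest. Manual grading is slow and
shows substantial inter-observer variability.

`cfstopo` implements a fully automatic grading pipeline:

1. **Preprocessing** — red channel (staining is green, so the red plane
   carries clean anatomical contrast), median filtering, contrast-limited
   adaptive histogram equalization (CLAHE), and removal of specular
   reflections detected by Otsu thresholding.
2. **ROI localization** — the sclera is segmented by Otsu thresholding;
   the corneal circle is the widest horizontal chord of the non-scleral
   region; the pupil is found with Daugman's integrodifferential operator;
   the ROI is the inferior 90° sector with apex at the pupil centre and
   radius reaching the bottom corneal edge, resampled to a normalized
   frame.
3. **Stain segmentation** — top-hat by reconstruction on the green ROI
   channel with a disk structuring element, thresholding, small-object
   removal, 8-connected labeling.
4. **Features** — 974 per image: 837 radiomic texture features (93 on each
   of 9 image forms), 9 morphological features of the segmented regions,
   and 128 multiscale dilation-graph topological features.
5. **Signature selection** — ANOVA filter, Pearson redundancy filter,
   backward elimination on a linear model of the grade, and decision-tree
   gini importance ranking.
6. **Grading** — SVM (Gaussian kernel), decision tree, boosting tree,
   naive Bayes, KNN and random forest on the selected signatures, with
   stratified 8:2 splitting and 10-fold cross-validation on the training
   split.

## The multiscale dilation graph

The distinctive feature family treats each segmented staining region's
centroid as a graph vertex. At a scale radius $r$ two vertices are joined
when the regions' dilations by the discrete disk
$\{(dr,dc): dr^2+dc^2 \le r^2\}$ share at least one pixel. Sixteen scales
($r = 4, 8, \dots, 64$ px in the normalized ROI frame) yield nested edge
sets; at each scale eight descriptors are computed: number of subgraphs,
average and maximum vertex degree, average vertex eccentricity, diameter,
average local clustering coefficient, giant-connected-component ratio, and
percentage of isolated vertices. Together they encode both the number of
lesions and their spatial aggregation: confluent or clustered staining
connects at small radii, scattered punctate staining only at large ones.

Implementation: dilation overlap is evaluated on the actual region masks,
not on a centroid-distance shortcut. Because the discrete disk is the
Euclidean ball, region $u$'s dilation at radius $r$ equals
$\{p: d(p, u) \le r\}$ for the exact Euclidean distance transform
$d(\cdot, u)$, so the *minimal connecting radius* of a pair is
$\min_p \max(d(p,u), d(p,v))$, computed once per pair on a canvas padded
by the largest scale; all sixteen edge sets follow by thresholding. A
windowed search (the intersection of the two bounding boxes expanded by an
upper bound on the optimum) keeps this linear in practice; the window
provably contains a minimizer whenever the pair connects within the scale
range. The test suite checks all 128 features against an independent
brute-force oracle that enumerates pixel pairs and candidate meeting
points.

Conventions for degenerate graphs, fixed here and asserted in tests:
eccentricity and diameter are computed within each vertex's own connected
component (an isolated vertex has eccentricity 0); the local clustering
coefficient of a vertex of degree < 2 is 0; the empty graph (a stain-free
image) yields all eight features equal to 0. Score-0 images therefore
carry an all-zero topological and morphological block, which is what makes
them trivially separable and is mirrored in the correlation analyses.

## Radiomic texture and morphological features

Texture is computed over the full ROI mask (not per lesion) on nine image
forms: the original green ROI, Laplacian-of-Gaussian at $\sigma = 1, 2, 3$
px, the four subbands of a one-level 2-D Haar decomposition (the basis is
the package's choice), and a rotation-invariant uniform local binary
pattern code image (radius 1, 8 neighbours, sampled on the discrete ring).
Each form yields 18 first-order statistics plus 75 gray-matrix features
(GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5) after fixed-bin-count
discretization (32 bins over the in-mask range; exposed in
`cfs_config()`). GLCM and GLRLM are averaged over the four 2-D directions
at distance 1. The within-form order lists the families alphabetically
with alphabetical features inside each family; this fixed order makes the
two externally anchored names land at their indices — `texture-<form>-15`
is the skewness and `texture-<form>-79` the GLSZM large-area low-gray-level
emphasis — and `feature_dictionary()` exports the full name-to-definition
map for audit.

The nine morphological features aggregate per-region area, perimeter
(chain-code length of the outer contour, diagonal steps weighted
$\sqrt2$), circularity $4\pi A/P^2$, and the short/long aspect ratio of
the minimum-area external rectangle (rotating calipers over the pixel
convex hull): mean and total area, mean and total perimeter-to-area ratio,
mean circularity, mean and total perimeter, mean aspect ratio, and the
region count.

## Tunable parameters

| Parameter | Default | Where | Notes |
|---|---|---|---|
| median kernel | 21 px at 1944-px frames, scaled with frame height, min 3 | `preproc_config()` | clinical value; scaled so the physical neighbourhood is preserved |
| CLAHE clip / tiles | 0.01, 8x8 | `preproc_config()` | conventional defaults; clip fraction mapped to the tile-histogram clip |
| pupil search box | side 0.35 R, radii 0.15-0.35 R, 1° arc sampling, $G_\sigma$ with $\sigma$ = 2 px | `pupil_search_spec()` | box/radius ranges are the protocol values; $\sigma$ is the package's choice |
| ROI frame | 596 x 1104, scaled with frame height | `cfs_config()` | `desk_config()` enlarges it 1.4x at sub-clinical frames (below) |
| top-hat structuring radius | 10 px in the ROI frame | `segment_config()` | protocol value; applied in the normalized frame |
| segmentation threshold | max(Otsu of in-mask top-hat, 0.15 x top-hat max, 10) | `segment_config()` | the fractional floor takes over when the top-hat histogram is effectively unimodal; the absolute floor suppresses stain-free noise |
| min region size | 5 px² | `segment_config()` | speckle suppression |
| ROI guard margin | 8 px erosion | `segment_config()` | keeps the bright limbal rim at the sector arc out of the detector |
| dilation scales | 4, 8, ..., 64 px | `scale_set()` | 16 scales, 8 features each |
| gray-level bins | 32 | `cfs_config()` | fixed bin count over the in-mask range |
| selection | alpha 0.05, \|r\| 0.9, p_out 0.05 | `select_features()` | package defaults, exposed |
| classifiers | RBF SVM (C = 1, gamma = 1/(d·var)), DT max 4 splits, boosting 30 rounds, KNN k = 10, RF 100 trees | `model_spec()` | protocol hyperparameters where stated |

## The synthetic-data generator

No public CFS image set exists, so every stage is validated on synthetic
anterior-segment images (`make_cohort()`): a bright sclera field, a darker
corneal disk and a dark pupil drawn in the red channel with 1-2 px soft
edges; staining dots as 2-D Gaussian green blobs whose half-peak radius is
the nominal dot radius (ground truth thresholds the noise-free stain layer
at half the nominal peak); saturated specular reflections; Gaussian sensor
noise. Grade scenes encode the OSS drivers: grade 1 scatters 1-5 dots;
grade 2 places 8-28 dots in loose clusters (sigma 0.24 R); grade 3 places
36-46 micropunctate dots in moderate clusters (0.17 R); grade 4 adds a
horizontal-leaning confluent streak — clinically, horizontal linear
staining is associated with incomplete blinking — and tightens the
clusters (0.13 R). Confluence in the ground truth is any region at or
above 1% of R²; dots stay clear of the central zone (0.35 R around the
pupil) unless a central modifier is intended. Every image's label is
re-derived from its own rendered mask, so the ground truth is consistent
by construction rather than by bookkeeping.

Cohorts additionally carry the photometric and morphological nuisance that
real slit-lamp photography shows, so that features cannot exploit an
unrealistically clean renderer: per-image exposure (0.7-1.35x), a green
channel gain (0.75-1.25x), linear illumination gradients, low-frequency
tear-film mottle, iris radial streaks visible through the cornea, mild
defocus (sigma up to 1 px), per-dot peak jitter (30%), irregular lesion
profiles (a connected core with dimmer satellite lobes, which the detector
may fragment), and faint fluorescein pooling — broad veiling haze plus a
dense field of sub-threshold specks that stay below both the ground-truth
half-peak level and the detector's contrast floor, polluting texture
statistics without creating detections. Under these conditions the
segmenter still reaches about 0.97 region recall and 0.95 precision
against ground truth, but region counting becomes realistically noisy.

What the generator does **not** emulate: eyelid and eyelash occlusion,
tear-film specular texture, vignetting and exposure variation, filament
morphology (a thin strand can be requested but is off by default, matching
the observation that filaments are rare), and the low-contrast ambiguous
edges of large real patches. Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under the stated geometry and
noise model — not clinical performance. The published clinical accuracy
figures depend on a private hospital dataset and are deliberately not
asserted anywhere in this package.

## Numerical choices and degenerate inputs

- **Coordinates**: (row, col), 1-based; downward = increasing row. In the
  integrodifferential operator's (x0, y0) notation, x0 is the column.
- **Daugman objective**: circular mean sampled at 1° with bilinear
  interpolation (the 1/2πr normalization is realized as the mean over arc
  samples); radial derivative as a first difference at 1 px steps;
  Gaussian smoothing along the radius with sigma 2 px; coarse 2 px centre
  grid with 3° sampling, then 1 px refinement at 1°. A flat objective
  raises a low-confidence flag rather than an error.
- **Reconstruction** is geodesic (iterated 3x3 dilation clipped by the
  mask, to stability). A smooth ramp is restored exactly in the interior;
  at the image border the opening clips the ramp's maximum, which is
  standard morphological behaviour and lies inside the ROI guard margin.
- **Reflection removal** operationalizes "brightest areas inside the
  cornea" before the cornea is known: above-Otsu components must be
  compact (at most 1% of the frame — the sclera is always larger) and
  near-saturated (component mean at least halfway from the threshold to
  the frame maximum — noise excursions are not).
- **Ties** in feature ranking break by canonical name order; all
  stochastic steps (splits, folds, learners) take explicit seeds, and the
  generator derives per-image seeds from one master seed, so every result
  in the package is exactly reproducible.
- **Degenerate texture inputs** (single gray level, empty marginals) take
  their defined limits — correlation 1, non-uniformity-normalized 1,
  coarseness capped at 1e6 — never NaN; this is asserted on every
  extraction.

## Problem sizes

The package is exercised at desk scale: synthetic frames of 220-300 px
(clinical geometry scaled down), cohorts of 400 images for the end-to-end
grading study, 50 random stain maps for the topological oracle suite, and
20 random eyes for pupil-recovery checks. At these frames `desk_config()`
enlarges the normalized ROI frame 1.4x over the proportional default:
proportional scaling of the clinical ROI would subsample the sector below
the Nyquist limit of micropunctate dots (about 1.5 px half-peak radius
after resampling), which degrades detection for a reason of resolution,
not contrast. At clinical resolution `cfs_config()` reproduces the
protocol frames exactly.

## Design choices where the design was open

- The "boosting tree, 30 training cycles" is realized as gradient-boosted
  depth-4 trees (30 rounds) rather than AdaBoost; the protocol names only
  the cycle count, and an established boosting implementation was
  preferred over a hand-rolled one.
- Backward elimination treats the 0-4 grade as a numeric response, as
  implied by its linear-model formulation.
- Selection runs once on the full training split, mirroring the single
  reported ranking; per-fold nested selection would be less optimistic and
  is noted as an extension.
- The cornea is located from the sclera's inner edges, while the ROI is
  re-anchored at the pupil centre; both stated procedures are implemented,
  and the sector radius uses the pupil-to-bottom-edge distance.
- Whether the structuring radius 10 applies before or after ROI
  normalization is unstated; it is applied in the normalized frame, where
  the scale set is also defined.
- "Central cornea" for the modifier means within 0.35 x R of the pupil
  centre (parameterized in `stain_spec()`), and the dot-count/patch
  distinction is an area threshold exposed as a parameter, since neither
  is given a pixel definition.

## Known limitations

- **The clinical superiority of topological features does not reproduce
  on the synthetic cohort.** The acceptance suite trains the SVM on the
  overall top-10 signature (held-out accuracy 85% at each of three seeds
  on the 400-image cohort) and compares the top-5 topological with the
  top-5 non-topological signature. On synthetic data the non-topological
  signature wins (about 78-81% vs 63-71%), and a family-pure diagnostic
  shows why: with near-exact segmentation of rendered geometry, raw
  morphological counts and areas encode the OSS count bands at least as
  faithfully as dilation-graph summaries, and the texture block retains
  robust blob statistics under every photometric nuisance model tried
  that did not also destroy overall gradability. The reported clinical
  advantage of topological features evidently rests on properties of real
  slit-lamp image statistics — anatomy-dominated texture and unreliable
  lesion counting — that this renderer does not reproduce. The
  corresponding acceptance assertion is left failing rather than weakened.
- Large low-contrast patches are only partially recovered by the top-hat:
  a structure wider than twice the structuring radius survives the
  opening and vanishes from the residual. This reproduces, rather than
  solves, a known weakness of the approach.
- The micro-averaged AUC treats the five one-vs-rest problems as pooled
  binary decisions; with strong class imbalance per-class AUCs are the
  more informative quantity.
- The exactly-equal precision and specificity columns in the reference
  protocol's tables cannot be reproduced from any standard averaging;
  macro-averaged definitions are used and the coincidence is not treated
  as a constraint.
- Interobserver agreement statistics (ICC) concern human raters and are
  out of scope for the automated pipeline.
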