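---
title: "Quantifying Haller's-layer vessels on en face OCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Haller's-layer vessels on en face OCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(choroidmetrics)
```

## The measurement problem

The large vessels of Haller's layer — the outermost choroidal layer —
are visible as a dark, branching phase on en face OCT slab images. In
central serous chorioretinopathy (CSC) these vessels are dilated, and
their running pattern about the horizontal fovea line tends to lose the
mirror symmetry that marks a subfoveal vortex-vein watershed. This
package turns an already-extracted slab image (nominally 512 × 512
pixels covering 7 × 7 mm, so 7/512 ≈ 0.0137 mm per pixel) into four
per-eye numbers:

* **vessel area** (mm²): area of the segmented dark phase;
* **vessel length** (mm): total length of the one-pixel centerlines;
* **mean vessel diameter** (mm): area divided by length — an
  area-weighted caliber summary;
* **symmetry index** (%): the share of centerline length running in the
  "natural oblique" direction, i.e. from the macula toward the
  upper-temporal vortex vein in the superior hemifield and toward the
  lower-temporal vortex vein in the inferior hemifield.

A cohort layer reproduces the statistics such a study needs: rank-sum
group comparisons, a Yates-corrected chi-square for sex distribution,
Spearman correlations against central choroidal thickness (CCT), and an
ROC analysis of mean vessel diameter with a Youden-index cutoff.

## Segmentation of the dark vessel phase

En face slabs are unevenly illuminated, so a global threshold bleeds
across the field. `binarize_enface()` uses local-mean (Niblack-style)
thresholding: a pixel is vessel when its (lightly smoothed) intensity
falls below the mean over a `window_px` neighbourhood minus `offset`.

Three parameters matter:

* `window_px` (default 51 px ≈ 0.7 mm): wide enough to straddle the
  largest Haller trunks, small enough to track illumination drift.
* `offset` (default 0.2 × the image's intensity SD): the threshold must
  sit *below* the local mean because the local mean itself is depressed
  wherever a vessel occupies much of the window. We calibrated the
  factor on synthetic scenes with known trunk width: at 0.1 × SD the
  edge transition ramp stays below threshold and every vessel dilates by
  about a pixel per side, which biases mean diameter upward by 10–20%
  at physiological calibers; 0.2 × SD removes most of that bias without
  eroding the dark phase.
* `smooth_px` (default 3): a single binomial (1, 2, 1)/4 pass per axis
  before thresholding. Without it, speckle makes pointwise thresholding
  mark roughly a third of background pixels as foreground — far above
  the percolation threshold, so the specks merge into clusters that
  survive any size filter. A box filter was rejected for this job: its
  wide ramp reintroduces the caliber dilation the offset calibration
  removed.

`denoise_mask()` then applies two size filters: 8-connected foreground
components below `min_component_px` (default 100 px) are deleted and
4-connected background holes below `min_hole_px` (default 100 px) are
filled. Holes are background components that do not touch the image
border.

## Centerlines, length, and diameter

`skeletonize_mask()` is Zhang–Suen thinning with two amendments, both
needed to make the downstream geometry well defined:

* deletions marked in parallel are applied *sequentially with a
  re-check*, because the textbook parallel schedule can erase an
  isolated 2 × 2 block entirely, violating "every component leaves a
  skeleton";
* a final pruning pass removes every non-endpoint pixel whose
  foreground neighbours form a single 8-connected group. Zhang–Suen
  leaves staircase corner pixels on oblique runs; they are redundant
  (their removal cannot disconnect anything) but give ordinary curve
  pixels three or more neighbours, which would flood the branch-point
  detector.

Vessel length is the step sum over unique 8-adjacencies of the skeleton
(1 px orthogonal, √2 px diagonal). A plain pixel count overestimates
diagonal runs by up to 41%; the step sum is exact for digital straight
lines. Mean diameter is area/length, with zero length an explicit error
distinct from the all-background case.

An image whose final mask is empty yields a record flagged
`valid = FALSE` with `NA` metrics rather than zeros — zeros would pass
silently into cohort statistics and drag every group mean toward the
origin.

## The symmetry index

The skeleton is cut at branch points (pixels with ≥ 3 skeleton
neighbours; adjacent branch pixels form one junction), leaving simple
open segments. Each retained segment is summarized by the chord between
its endpoints:

* **orientation**: the chord's angle to the horizontal in (−90°, 90°],
  computed in a laterality-normalized frame (+x temporal, +y superior;
  left-eye images are mirrored first, so one angular rule serves both
  eyes). Normalization happens *before* any raster operation because
  thinning is scan-order dependent; mirroring afterwards would break
  exact OD/OS equivalence.
* **hemifield**: by the chord midpoint's side of the horizontal fovea
  line (midpoints exactly on the line count as inferior — any fixed rule
  works, and this one keeps the left/right mirror invariance exact).
* **natural oblique**: orientation inside the open quadrant (0°, 90°)
  for superior segments, (−90°, 0°) for inferior ones. Exactly
  horizontal or vertical chords are not natural under the default open
  bounds; `symmetry_config(include_bounds = TRUE)` and `band_deg` let
  the band be narrowed or closed, since the original angular tolerance
  is not published.

Closed loops (no endpoints) and fragments shorter than
`min_segment_px = 5` px (≈ 0.07 mm) are discarded but counted; sub-5-px
pieces are thinning artifacts at this pixel pitch. The symmetry index is
100 × (natural segment length)/(total retained length).

## The synthetic data generators

No image data are distributed with the study this package models, so
the generators are first-class, tested code — they define the conditions
under which every pipeline claim is verified.

**Scenes** (`generate_vessel_image()`): dark vessel trunks on a brighter
stromal background with additive Gaussian noise, rounded to an 8-bit
bitmap. Trunks emanate near the horizontal fovea line — the vortex-vein
watershed, which real Haller trunks approach but do not cross — and run
away from it with a fixed base angle drawn from 20–70° plus per-step
jitter (`tortuosity_deg`, default 5°). Start columns are stratified so
trunks spread across the field instead of clustering. The defaults
(512 px, 12 trunks per hemifield, width 11 ± 2 px ≈ 0.15 mm, vessel 80
vs background 200 intensity, noise SD 15) were chosen once to emulate
the appearance and caliber scale of real slabs. `symmetry_fraction` is
an *exact* per-hemifield quota of natural-oblique trunks rather than a
Bernoulli probability: the dial then equals the scene's ground truth up
to rounding, so recovery tests measure the pipeline, not binomial noise.
The generator returns the exact pre-noise mask and the drawn trunk table
as oracles.

What the scenes do **not** emulate: OCT speckle physics (noise is
i.i.d. Gaussian), shadowing from overlying layers, slab-selection
errors, curvature-induced intensity gradients, and physiological
branching hierarchies (trunks are independent random walks — the
metrics depend only on width and orientation statistics, so this is
deliberate). Passing recovery tests therefore show the measurement chain
is unbiased under controlled geometry, not that segmentation is robust
to every real-world artifact.

**Cohorts** (`generate_cohort()`): per-eye metric tables for the three
study groups (healthy control, unaffected fellow eye, CSC eye; 41 eyes
each by default) with the published means and SDs for diameter, length,
symmetry index and CCT. Marginals are truncated normal (metrics are
positive; the index lives in [0, 100]); coupling is a Gaussian copula
with a one-factor structure in which CCT is the factor and each metric's
loading is its Spearman target (converted to the Pearson scale by
2·sin(πρ/6)). The one-factor form is always positive semi-definite and
encodes conditional independence of the metrics given CCT — the most
parsimonious structure consistent with the published pairwise
correlations. Vessel area is derived as diameter × length rather than
sampled: the downstream analyses (ROC cutoff, diameter–CCT correlation,
group significance) all key on the diameter marginal, which this choice
reproduces exactly, while keeping every record self-consistent
(diameter = area/length identically). The fellow-eye symmetry–CCT
correlation is used with a negative sign, following the direction of
effect the source describes for it.

## Statistical layer

Standard tests are delegated to base R: `wilcox.test` (exact when the
combined sample is ≤ 16 without ties, otherwise the continuity-corrected
normal approximation with tie correction), `chisq.test` with Yates
correction (the corrected test reproduces the published sex-distribution
p-value from its counts; the uncorrected one does not), and `cor.test`
for Spearman with the asymptotic t approximation. No multiple-testing
correction is applied, matching the analysis being reproduced.

`roc_youden()` is implemented here because its conventions are pinned:
classification is "positive iff value > cutoff" (the published quadrant
table is phrased as "diameter > 0.153 mm"), every observed value is
evaluated as a cutoff, the Youden maximum breaks ties toward the larger
cutoff (higher specificity), and AUC is trapezoidal. The test suite
checks it against an independently coded brute-force scan and checks the
AUC against `pROC`.

## Numerical and degenerate-input choices

* Orientation of a vertical chord is 90° (not −90°); endpoint order
  never matters.
* A constant image with a positive offset binarizes to an empty mask —
  a valid result, not an error; an image smaller than the threshold
  window is an error.
* Zero retained segments make the symmetry index an error (undefined),
  as does zero skeleton length for the diameter.
* All generators take an integer seed and restore the caller's RNG
  state; identical seeds give bit-identical output.
* Floating-point ties in the Youden scan are resolved with a 1e-12
  tolerance before the larger-cutoff rule.

## Problem sizes used in the checks

The package's own verification runs at the native 512-px scene scale for
parameter-recovery claims (diameter within 15% of truth; symmetry index
within 10 points of the dial across s ∈ {0, 0.25, 0.5, 0.75, 1}), at
reduced 160–256-px scenes for structural invariants where scale is
irrelevant, with 1000 random instances for the ROC oracle equivalence,
full enumeration up to 8 + 8 for the exact rank-sum test, 10,000
simulations for type-I calibration, and 100 replicate cohorts of 41 eyes
per group for the direction-of-effect reproduction.

## Known limitations

* Mean diameter is an area-weighted network summary: where trunks cross,
  overlap area is counted once while centerlines merge, so dense
  networks read a few percent wide. The same is true of the original
  measurement definition; comparisons between eyes are unaffected.
* The symmetry index inherits the hemifield rule for midline-crossing
  segments (midpoint side); segments that straddle the fovea line are
  not split.
* Binarization assumes dark vessels on a brighter stroma with slowly
  varying illumination; slabs dominated by shadow artifacts will
  segment poorly regardless of parameters.
* The published per-eye data are not available, so cohort-level claims
  are verified on simulated cohorts with the published moments and
  correlation structure — they demonstrate that the statistical layer
  reproduces the reported direction and rough operating point of the
  effects, not the exact printed values.
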