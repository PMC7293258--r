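# choroidmetrics

Quantitative morphometry of the large choroidal vessels (Haller's
layer) on en face OCT slab images, for researchers studying
pachychoroid-spectrum disease such as central serous chorioretinopathy
(CSC).

Given a grayscale en face image of the top slab of Haller's layer
(nominally 512 × 512 px over 7 × 7 mm), the package segments the dark
vessel phase by local-mean thresholding, thins it to one-pixel
centerlines, and reports per eye:

* **vessel area** `A` (mm²) — area of the binarized dark phase,
* **vessel length** `L` (mm) — total centerline length (step sum: 1 px
  orthogonal, √2 px diagonal),
* **mean vessel diameter** `D = A / L` (mm),
* **symmetry index** (%) — the centerlines are cut into branch-free
  segments at branch points; a segment is a *natural oblique vessel*
  when the chord between its endpoints points from the macula toward
  its hemifield's temporal vortex vein (orientation in (0°, 90°) above
  the horizontal fovea line, (−90°, 0°) below it, in a
  laterality-normalized frame). The index is
  100 × Σ length(natural) / Σ length(all segments). High values mean a
  mirror-symmetric running pattern, consistent with a vortex-vein
  watershed beneath the fovea.

A cohort layer covers the associated statistics — Mann–Whitney U group
comparisons, Yates-corrected 2 × 2 chi-square, Spearman correlation
against central choroidal thickness, and ROC analysis of mean vessel
diameter with the Youden-index cutoff (positive iff `D > cutoff`, ties
toward higher specificity). Seeded generators produce synthetic vessel
scenes with exact ground truth and per-eye metric cohorts with
configurable group means, SDs, and rank-correlation structure, so the
whole pipeline is testable without patient data.

## Worked example

```r
library(choroidmetrics)

# a synthetic en face scene: 512 px / 7 mm, 12 trunks per hemifield,
# 80% of trunks in the natural oblique orientation
scene  <- generate_vessel_image(vessel_scene_params(symmetry_fraction = 0.8, seed = 42))
metrics <- compute_eye_metrics(scene$image)
metrics
#>     id group eye_side vessel_area_mm2 vessel_length_mm mean_diameter_mm
#> 1 <NA>  <NA>       OD        11.86607         72.39585        0.1639053
#>   symmetry_index_pct cct_um valid
#> 1           81.51961     NA  TRUE
```

The measured caliber (0.164 mm ≈ 12 px) matches the generator's 11 ± 2
px trunk width, and the symmetry index (81.5%) recovers the 0.8 dial.

The end-to-end demo simulates a three-group cohort (control / fellow /
CSC, 41 eyes each, published group moments), compares the metrics, and
derives a diagnostic cutoff for the mean vessel diameter:

```r
demo <- run_end_to_end_demo(seed = 42)
cat(tail(demo$report, 4), sep = "\n")
#> ROC of mean vessel diameter, csc vs control:
#>   AUC = 0.833
#>   Youden cutoff = 0.1642 mm (J = 0.634)
#>   sensitivity 73.2%, specificity 90.2% at cutoff
```

The cutoff lands between the control (0.144 mm) and CSC (0.185 mm)
group means, as it must for a usable separator.

For batch work on image files there is a thin CLI
(`inst/cli/choroidmetrics`) with subcommands `analyze`, `simulate`,
`simulate-cohort`, `cohort`, `roc` and `demo`; every run writes an
`effective_config.json` provenance record next to its outputs.

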