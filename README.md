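# maculaquant

Quantification of the macular inner retina from structural OCT and en
face OCT angiography (OCT-A), for studies of thyroid-associated
ophthalmopathy (TAO) and dysthyroid optic neuropathy (DON) — or any
cohort study comparing regional layer thicknesses and capillary
densities around the fovea.

The package implements, end to end:

* **Layer segmentation and thickness mapping.** Nine intra-retinal
  boundaries per B-scan are traced by a gradient-cost shortest path
  (column-wise dynamic programming; for boundary *b* with depth profile
  *y_b(x)*, the path minimises Σ_x c(y(x), x) subject to
  |y(x+1) − y(x)| ≤ s), with lateral magnification corrected by
  Bennett's abbreviated relation q(AL) = 0.01306·(AL − 1.82). Layer
  thickness is boundary subtraction times the axial scale; 18 radial
  meridians are interpolated onto a fovea-centered map, and means are
  reported for NFL, GCL+IPL, GCC (= NFL + GCL+IPL), INL+ORL and total
  retina over the central disk, the total annular zone (TAZ) and four
  quadrant sectors.
* **Retinal capillary density (RCD).** En face angiograms (SSI > 40)
  are upsampled bicubically to 1024², the foveal avascular zone is
  delineated by a Canny-seeded Chan–Vese level set on the local
  perfusion-density field, a noise floor (FAZ mean + 2 SD) scaled ×3
  plus a 25 µm width filter isolates large vessels, adaptive
  thresholding yields the all-vessel map, and the capillary-only map is
  their exact set difference. RCD(region) = 100 · |capillary ∩ region| /
  |region| for the TAZ, six annular rings C1–C6 (diameters 0.92–2.50
  mm) and four sectors.
* **Cohort statistics.** Eye-clustered three-group comparisons
  (cluster-robust HC1 inference on patient clusters), Pearson
  structure–perfusion correlations, empirical Mann–Whitney and binormal
  AUC (Φ(|Δμ|/√(σ₁²+σ₂²))), and composite indices from two-predictor
  logistic regression with Youden-point operating characteristics.
* **Synthetic data with ground truth.** Seeded B-scan phantoms,
  angiogram phantoms (known FAZ, vessel masks and per-region capillary
  fractions) and three-group cohorts parameterized by the published
  group summary statistics (`reference_stats()`).

## Worked example

Quantify a synthetic angiogram with known truth (target capillary
fraction 63.7 % of the TAZ):

```r
library(maculaquant)

ph   <- make_angiogram_phantom(capillary_fraction = 0.637, seed = 42)
prof <- rcd_profile(ph$angiogram)
prof
#> # A tibble: 11 × 4
#>    eye_id  layer region rcd_percent
#>  1 phantom SRCL  TAZ           64.2
#>  2 phantom SRCL  C1            67.1
#>  3 phantom SRCL  C2            66.2
#>  ...
#> 11 phantom SRCL  N             64.6
attr(prof, "faz")
#> <faz_boundary> area 0.280 mm^2, center (513.9, 512.4)
```

The TAZ density (64.2 %) recovers this phantom's realized truth
(63.7 %) to within half a percentage point, and the detected FAZ area
(0.280 mm²) is within 1 % of the phantom's true disk (0.282 mm²). Ring and sector values are exact area-weighted partitions
of the TAZ value.

Cohort-level analysis on a simulated three-group cohort (38/36/38 eyes
drawn at the published group statistics):

```r
coh <- make_cohort(seed = 1)
tidy(group_compare(coh, "DRCL_TAZ", alpha = 0.01))
#>   measure  group_a group_b estimate    se statistic  p_value significant
#> 1 DRCL_TAZ control nonDON      3.49  1.37      2.56 0.0129   FALSE
#> 2 DRCL_TAZ control DON         5.92  1.62      3.64 0.000537 TRUE
#> 3 DRCL_TAZ nonDON  DON         2.42  1.64      1.48 0.144    FALSE

rep <- roc_report(coh)   # 17 single + 10 composite ROC rows
rep[rep$kind == "composite", c("indicator", "auc", "sensitivity", "specificity")]
#>   GCC_TAZ + SRCL_C6 0.937        84.2        94.7
#>   GCC_TAZ + DRCL_C6 0.874        81.6        78.9
#>   GCC_S   + SRCL_C6 0.927        89.5        92.1
#>   ...
```

Here the control–DON contrast of deep-layer TAZ density (estimate
5.9 %, cluster-robust p = 5 × 10⁻⁴) is flagged at the family α = 0.01,
while the smaller contrasts are not in this single draw; composite
indices (GCC thickness + C6 density) separate DON eyes from controls
with AUCs near 0.9. `run_eye()` assembles per-eye records from images,
`run_cohort()` writes the full report bundle (comparison tables,
correlations, ROC, manifest) as CSV.

A command-line wrapper (`inst/cli/maculaquant-cli.R`) exposes
`segment-bscan`, `quantify-angio`, `run-eye`, `cohort-report` and
`simulate` subcommands over the same functions.

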