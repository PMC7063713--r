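---
title: "Methods: macular layer thickness and capillary density quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macular layer thickness and capillary density quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maculaquant)
```

## Scope

`maculaquant` quantifies the macular inner retina in thyroid-associated
ophthalmopathy (TAO) and dysthyroid optic neuropathy (DON) studies — and
in any comparable macular imaging study — from two inputs:

* **structural OCT B-scans** acquired as radial scans through the fovea
  (18 meridians over 180°), from which intra-retinal layer thicknesses
  are measured, and
* **en face OCT angiograms** (3 × 3 mm, 304 × 304 px) of the superficial
  and deep retinal capillary layers (SRCL, DRCL), from which regional
  retinal capillary density (RCD, %) is measured.

A statistics layer reproduces the cohort-level analyses such studies
report: eye-clustered three-group comparisons, structure–perfusion
correlations, and single/composite ROC analysis. Because per-eye patient
data of the motivating study are not deposited, the package ships seeded
generators for every input with machine-readable ground truth, and all
validation rests on those phantoms plus closed-form checks of the
published summary statistics.

## Region geometry

All regional analysis happens on a fovea-centered isotropic grid
(`fovea_grid()`). The macular analysis disk is 2.5 mm in diameter and is
divided into

* the central 0.60 mm disk `C`, coinciding with the fixed foveal
  avascular zone (FAZ) disk,
* the total annular zone `TAZ` (0.60–2.50 mm),
* six annular rings `C1..C6` with outer diameters 0.92, 1.23, 1.55,
  1.87, 2.18, 2.50 mm (equally spaced *diameters*, not equal areas), and
* four quadrant sectors `S`, `T`, `I`, `N` bounded by the two 45°
  diagonals.

A pixel belongs to a region iff its **center** does, with half-open
radial intervals `[inner, outer)`, so rings and sectors partition the
annulus exactly in pixel arithmetic — the partition identities (TAZ
density equals the area-weighted ring mean and sector mean) are exact,
not approximate. Sector orientation uses 0° = image up; temporal/nasal
assignment needs the eye's laterality plus one convention flag
(`temporal_side`, default `"left"` for a right eye displayed in fundus
orientation), because image orientation metadata is device-specific.
Whether the thickness map and the angiogram use identical angular
boundaries is not standardized; the package deliberately shares one
geometry between both.

## Layer segmentation

Nine intra-retinal boundaries are traced per B-scan by a gradient-cost
shortest path:

1. **Cost** (`gradient_cost()`): after light Gaussian smoothing
   (`smooth_sigma`, default 1 px), the vertical backward difference is
   taken; cost is low where the signed gradient matches the boundary's
   polarity (dark→bright or bright→dark), normalized to (0, 1] and
   strictly positive. A backward difference is used deliberately: a step
   between rows *r−1* and *r* yields its full magnitude at row *r*, so
   edges localize without the half-pixel bias a central difference
   introduces.
2. **Tracing** (`trace_boundary()`): the minimum-cost left-to-right path
   with one node per column and vertical moves of at most `max_step`
   (default 2) px, solved by column-wise dynamic programming (equivalent
   to Dijkstra on the layered DAG, chosen for determinism and speed).
   Ties break toward the smaller row index, making results
   bit-reproducible; the tracer is verified against exhaustive path
   enumeration on small instances.
3. **Schedule** (`segmentation_schedule()`): the inner limiting membrane
   and the outer retinal boundary are traced first (largest contrast),
   then the outer-plexiform transition, then the remaining interior
   boundaries, each restricted to the band between already-found
   neighbours. The band excludes `band_margin` px (default
   `3 * smooth_sigma`, at least 2) on each side of a traced neighbour so
   a strong neighbour's blur-spread edge cannot capture the path. The
   order/polarity schedule is a configuration table, since the exact
   anatomical recipe is device- and pipeline-specific; the default
   matches the intensity ordering of the phantom model below.
   Non-crossing is guaranteed by construction and asserted.

Lateral scale is corrected for ocular magnification with the abbreviated
axial-length relation *q*(AL) = 0.01306·(AL − 1.82) mm/deg; the factor
*q*(AL)/*q*(ref) multiplies the nominal lateral scale (reference length
configurable, default 23.95 mm). Thickness is boundary subtraction times
the axial scale. Reported layers are NFL (boundaries 1–2), GCL+IPL
(2–3), GCC (1–3, so GCC = NFL + GCL+IPL holds to machine precision),
INL+ORL (3–9) and total retina (1–9).

The 18 meridional thickness profiles are interpolated onto the
fovea-centered map linearly in angle (two adjacent meridians) and
linearly in radius; a pixel lying exactly on a meridian takes that
profile's value; pixels beyond the scanned extent are missing and are
excluded from regional means, never imputed. The central `C` value is
the disk mean, not a point value.

## Capillary density

For each angiogram that passes the quality gate (signal strength index
strictly greater than 40):

1. **Upsampling**: bicubic interpolation (Keys kernel, a = −0.5,
   edge-clamped, separable) from 304² to 1024² (≈2.93 µm/px).
2. **FAZ detection** (`detect_faz()`): flow pixels of a central 1.5 mm
   window are binarized against the noise level of the avascular core
   (mean + 2 SD of the central 0.2 mm), then box-averaged at the
   capillary-spacing scale (radius 0.065 mm) into a perfusion-density
   field: near zero inside the FAZ, at plexus density outside, ramping
   linearly across the interface. A Canny edge map of this field centers
   a 0.25 mm seed disk; a morphological Chan–Vese level set (two-phase,
   region-based, with the curve-smoothing step implemented as
   alternating binary opening/closing) localizes the interface, keeping
   the center-connected component and filling holes so the region is
   simply connected; the final contour is re-thresholded at the
   half-crossing between the deep-core and far-surround levels, which is
   unbiased for straight edges and leaves only a small curvature bias.
   If the density contrast is absent (fully perfused image) or the area
   leaves [0.01, 1.5] mm², a fixed 0.60 mm disk is substituted with a
   warning. The detected contour is reported as metadata only — the
   fixed 0.60 mm disk defines both the noise floor region and the TAZ
   exclusion, because the noise floor must come from a region that is
   avascular by construction rather than by estimation.
3. **Noise floor** (`noise_floor()`): mean + k·SD (default k = 2) of the
   fixed foveal disk on the upsampled image.
4. **Large vessels** (`global_threshold()`): binarize at noise floor ×
   `factor` (default 3) and keep components whose maximal inscribed
   width — twice the distance-transform maximum, attained on the medial
   axis — reaches `min_width_um` (default 25 µm).
5. **All vessels** (`adaptive_threshold()`): the default rule is a
   local-midrange (Bernsen-style) threshold: a pixel is on iff it
   strictly exceeds the midpoint of the local robust minimum and maximum
   over the window (default 0.25 mm), computed on a lightly smoothed
   copy, with intensities above the 0.9 quantile of non-large pixels
   winsorized first so bright large vessels do not inflate the local
   maximum. The midrange tracks the midpoint of the two intensity
   classes, so it cuts the partial-volume border of upsampled vessels
   symmetrically and is an approximately unbiased area estimator at any
   vessel density — a plain local-mean threshold (available as
   `method = "mean"`) sits at the density-weighted average instead and
   systematically undercounts dense plexuses. `offset` is *added* to the
   local threshold, so raising it can only lower every regional density
   (a useful monotonicity invariant). The union with the large-vessel
   map is enforced afterwards so the subset invariant holds exactly.
6. **Subtraction** (`capillary_map()`): the capillary-only map is the
   exact set difference of the two binary maps.
7. **RCD** (`rcd()`, `rcd_profile()`): percent of each region's pixels
   covered by the capillary-only map. Large-vessel pixels are excluded
   from the numerator but remain in the denominator ("proportion of the
   measured area"); a config switch (`rcd_numerator = "all"`) includes
   them in the numerator instead. All thresholds compare with strict
   `>`, and the pipeline contains no randomness, so identical inputs
   give bit-identical maps.

## Synthetic data

`make_bscan_phantom()` renders eight layers between nine parametric
boundary curves (flat, sinusoidal, or a foveal-pit profile), blurs, and
applies multiplicative speckle. The default layer intensity profile
(vitreous 10; NFL 200; GCL+IPL 110; INL 60; OPL 130; ONL 30; inner
segments 80; outer segments 140; RPE 230; below 20, on a 0–255 scale)
was chosen once so that each interface is, within its tracing band and
polarity, the strongest available edge — mirroring the real contrast
ordering where the ILM and RPE dominate. It does not emulate depth-
dependent signal decay, shadowing, or motion artifacts.

`make_angiogram_phantom()` draws a zero-flow FAZ (disk, ellipse, or
mildly irregular outline), a few wide bright vessels (default 4 ribbons,
32–48 µm) routed around the center, and a capillary mesh modelled as the
threshold set of a band-pass (difference-of-Gaussians) noise field, with
the level chosen so the realized TAZ area fraction matches the target
exactly (±1 px rounding). The band-pass construction keeps the mesh
locally homogeneous — raw low-pass noise produces low-frequency density
patches that no boundary detector could attribute to signal or chance.
The mesh scale (`mesh_sigma_px = 2.2` at 304 px, features ≈30–40 µm)
represents a point-spread-broadened capillary plexus as rendered by
OCT-A, not anatomical capillary calibre; large vessels are separated
from capillaries by intensity (250 vs 100 against background 25), as in
real angiograms where large vessels saturate the decorrelation signal.
The model deliberately omits projection artifacts, vessel trees/loops,
and flow-dependent intensity variation — only area fraction matters to
RCD, so passing recovery tests demonstrates correct area accounting, not
robustness to those artifacts.

`make_cohort()` samples a three-group cohort (default 38/36/38 eyes,
the published cohort sizes) with a configurable fraction of bilateral
patients (default 0.65, matching 74 eyes from 44 TAO patients ≈ 68 %
bilateral). Each of the 52 regional measures is normal within group at
the published means/SDs (`reference_stats()`), with a shared
within-patient latent component giving inter-eye correlation
`rho_eye = 0.6` — a plausible value; the study does not report one — and
a cross-measure correlation of 0.312 between GCC TAZ thickness and SRCL
TAZ density, the published pooled-TAO value. Values truncate at 0
(negligible at these coefficients of variation). Covariates (age, sex,
axial length, IOP, BCVA, visual-field mean defect, clinical activity
score) follow the published demographic table.

## Cohort statistics

* **Group comparison** (`group_compare()`): cell-means linear model over
  eyes; the overall test and the three pairwise contrasts use
  cluster-robust (CR1/HC1) standard errors clustered on patient — the
  implementable reading of "generalized estimating adjustment for
  inter-eye correlation" — with a t/F reference on (clusters − groups)
  degrees of freedom. One-eye-per-patient cohorts reduce to ordinary
  one-way ANOVA inference up to the small-sample factor. No additional
  multiplicity correction is applied to the pairwise tests; instead the
  family significance level is set to 0.01 for the thickness and RCD
  families (0.05 elsewhere), mirroring the study's convention. Type-I
  error is verified by simulation to be within ±2 pp of nominal at both
  levels.
* **Correlation** (`pearson()`): product-moment correlation with
  two-sided p, pooling both TAO groups' eyes for the
  structure–perfusion analysis.
* **ROC** (`empirical_auc()`, `single_roc()`): Mann–Whitney AUC with
  midrank tie handling, verified against exhaustive pair enumeration;
  orientation is chosen so AUC ≥ 0.5 with the direction recorded, since
  thickness falls while the ROC treats it as a separator.
  `binormal_auc()` gives the closed form Φ(|Δµ|/√(σ₁²+σ₂²)) used to
  cross-check empirical AUCs against published group statistics.
* **Composite index** (`composite_index()`): two-predictor logistic
  regression by maximum likelihood; the composite score is the fitted
  probability, whose in-sample AUC provably never falls below either
  marginal AUC. The operating point maximizes the Youden index on the
  probability ROC; the one-cutoff-per-component report gives the
  component values of the observation at that operating point (an
  interpretation — a probability-threshold report is available via
  `cutoff_mode`). Complete or quasi-complete separation is detected from
  the fitting warnings and handled by an internal ridge-penalized IRLS
  refit (λ = 0.01 on the slopes), flagged in the result.
* **Report** (`roc_report()`): 17 single-indicator rows (GCC: TAZ and
  four sectors; SRCL and DRCL density: TAZ, C6 and four sectors) and 10
  composite rows (five GCC regions × the C6 density of each capillary
  layer), DON vs control.

## Numerical choices and degenerate inputs

* All image thresholds use strict `>`; path and AUC ties have
  deterministic rules; every simulation takes an explicit seed. Reruns
  are byte-identical.
* Empty masks, empty groups, zero-variance correlations, missing SSI,
  bands that cannot be connected, and out-of-range axial lengths raise
  errors naming the offending quantity; a gated angiogram nulls the
  density fields of the eye record rather than failing the whole eye
  (strict mode errors instead).
* The FAZ detector falls back to the fixed 0.60 mm disk (with a
  warning and a flag) rather than returning a degenerate contour.

## Validation problem sizes

The shipped tests run the tracer-vs-enumeration oracle on 100 random
instances (≤12 rows × ≤8 columns); boundary recovery on speckled
phantoms (MAE ≤ 2 px demanded, ≤0.5 px typical); density recovery on 50
phantoms spanning true densities 0.50–0.80 (mean signed error within
±2 pp, 95th percentile of |error| ≤ 4 pp); FAZ area on disk, ellipse and
irregular shapes (≤7 %); type-I calibration on 1,000 null cohort
replicates; and Monte-Carlo/binormal AUC agreement at 10,000 samples per
class (|Δ| ≤ 0.01). These sizes were chosen to bound each estimator's
error meaningfully while keeping the default check runnable on a laptop
in a few minutes.

## Known limitations

* The segmentation schedule assumes the standard contrast ordering of a
  healthy or mildly affected macula; severe disruptions (edema, atrophy)
  would need a re-tuned schedule.
* The density pipeline consumes rendered en face angiograms; it does not
  model or remove projection artifacts, nor recompute decorrelation from
  raw spectra.
* Phantom-based validation demonstrates correct geometry and area
  accounting under the stated noise model; it cannot certify performance
  on real device images, which add speckle correlation, vessel shadows
  and motion artifacts outside the model.
* The cluster-robust comparison is the package's reading of an eye-
  cluster adjustment; with very few patients per group its small-sample
  behaviour (t on clusters − groups df) is approximate.
* Peripapillary nerve-fiber analysis, choroidal sublayers and
  skeleton-based vascular metrics (length density, fractal dimension)
  are out of scope.
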