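---
title: "Quantitative meniscus morphometry and progression analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative meniscus morphometry and progression analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menisq)
```

## The measurement problem

Meniscus extrusion — displacement of the meniscus beyond the external margin
of the tibial plateau — and loss of tibial plateau coverage are candidate
imaging biomarkers for structural progression of knee osteoarthritis.
`menisq` computes quantitative 3D measures of meniscus position and
morphology from voxelized coronal segmentations of one femorotibial
compartment, classifies knees as structural progressors or non-progressors
from longitudinal cartilage-thickness and joint-space-width data, builds
caliper-matched case-control sets, and summarises group differences with
paired statistics.

A `segmented_compartment` holds a solid binary meniscus mask on a
`(y, z, x)` grid — coronal slice, inferior-superior, internal-external —
plus the tibial plateau footprint over `(y, x)` (the total subchondral bone
area, ACdAB, projected onto the tibial plane) and the voxel spacing,
defaulting to the coronal DESS reconstruction geometry of
1.5 mm slice thickness and 0.37 mm in-plane. Segmentation workflows often
delineate the meniscus surfaces (tibial, femoral, external) separately;
this package stores the solid region and derives the tibial surface as the
per-column projection, which is fully recoverable from a solid voxel mask
and keeps the phantom generator and the file format simple.

## Position and morphology measures

Per coronal slice, the signed extrusion distance is

$$e(y) = \left(x^{\max}_{\text{meniscus}}(y) - x^{\max}_{\text{plateau}}(y)\right)\cdot s_x,$$

the offset between the external-most occupied cells of the meniscus
footprint and the plateau footprint, scaled by the in-plane spacing. The
margin is the external-most occupied cell, not a sub-voxel contour fit:
that keeps every measure exactly reproducible by integer cell enumeration,
which is how the test suite verifies them. Aggregates are:

* **Mean / maximum extrusion (mm)** — mean and maximum of $e(y)$ over all
  slices where *both* structures are present. Slices lacking either
  structure are excluded, not zero-imputed; zero-imputation would bias the
  mean toward zero by an amount depending on slice thickness. Negative
  values (meniscus margin internal to the plateau margin) are kept — lateral
  menisci commonly average below zero — so no truncation is applied.
* **Central-slice surrogates** — the same mean over the central slice and
  the central five slices of the slices containing meniscus. The central
  index is `floor((first + last) / 2)`; with an even slice count this picks
  the anterior of the two middle slices, a deterministic tie-break that the
  measurement convention leaves open.
* **Extrusion area (%)** — meniscus footprint cells outside the plateau, as
  a percentage of the meniscus footprint.
* **Tibial plateau coverage (%)** — plateau cells under the meniscus
  footprint, as a percentage of the plateau. Cell areas are uniform, so
  both reduce to cell counts.
* **Height (mm)** — per occupied `(y, x)` column, voxel count times
  z-spacing; mean and maximum over occupied columns.
* **Width (mm)** — per slice, `(x_max - x_min + 1) * s_x` over the
  footprint; mean over slices containing meniscus.
* **Volume (ml)** — voxel count times voxel volume.

Measures requiring a non-empty structure raise typed conditions
(`menisq_empty_meniscus`, `menisq_undefined_slice`, …) rather than
returning zero, so cohort aggregation can distinguish "absent" from a true
zero.

## Progression classification and matching

The smallest detectable change (SDC) converts test-retest variability into
a threshold above which an observed longitudinal change is unlikely to be
measurement noise: `compute_sdc()` returns $1.96 \times SD$ of the paired
test-retest change differences (equivalently $1.96\sqrt{2}\,\mathrm{SEM}$).
The published thresholds — 102 µm for medial and 92 µm for lateral
femorotibial cartilage-thickness loss, 328 µm for medial minimum joint
space width — are injected as constants in `sdc_thresholds()`, not
recomputed, so the classification never drifts from the published rule.

A knee is a **progressor** when both its medial cartilage-thickness loss
and its medial minJSW loss strictly exceed their thresholds, and a
**non-progressor** when medial thickness, minJSW and lateral thickness
losses all fail to exceed theirs; everything else is indeterminate.
"Exceeding" is read as a strict inequality, so a loss exactly at the
threshold is compatible with non-progression; `strict = FALSE` flips the
convention for sensitivity analysis. Losses are computed in micrometres
from mm-valued inputs (fixed factor 1000). Records missing a required
field are excluded with a reason code rather than silently dropped.

Eligibility retains Kellgren-Lawrence grades 2-3 (definite but not
end-stage radiographic osteoarthritis). Matching is 1:1 with exact
agreement on sex and KLG and calipers of ±3 cm body height, ±5 kg/m²
BMI and ±5 WOMAC pain points. Because no particular matching algorithm is
canonical for this design, `match_pairs()` solves a weighted bipartite
matching (via igraph) whose edge weights encode *first* maximum
cardinality, *then* minimum total caliper-normalized distance
$\sum |\Delta|/\text{caliper}$ — a deterministic optimum given the input
order. A greedy nearest-eligible-control variant is provided for
sensitivity analysis. The test suite checks the optimal matcher against
exhaustive search on instances up to 8×8.

## Paired statistics

Group contrasts use the mean within-pair difference with its paired-t 95%
confidence interval and p-value, and Cohen's D as effect size in the
pooled-SD two-group form

$$d = \frac{\bar{x}_1 - \bar{x}_2}{\sqrt{(s_1^2 + s_2^2)/2}},$$

the variant that can be verified directly against published group means
and SDs (a paired-design D would need the SD of the differences, which
summary tables rarely print). When working from a printed table, the
difference of the rounded group means can disagree with the separately
printed difference cell; `cohens_d_pooled()` therefore accepts the
difference as an optional numerator. Correlation between entire-meniscus
and central-slice measures uses Pearson's r with variance explained
reported as `round(100 r²)`.

Rounding is applied only at the presentation layer
(`format_comparison_table()`): half-away-from-zero at 1 decimal for
measures and 2 for effect sizes, with p-values below 0.005 displayed as
"< 0.01". No multiple-testing correction is applied, matching the analysis
convention the tables follow. Zero-variance differences yield a degenerate
zero-width CI and an undefined (NA) p-value rather than an error at the
table level.

## Synthetic data

Two phantom families provide ground truth without clinical data.

The **box phantom** is a rectangular plateau and meniscus slab with a
per-slice external offset; every measure has a pencil-and-paper closed
form, and the morphometry code must match it exactly.

The **C-phantom** is an annulus-sector wedge (thickness rising linearly
from the inner to the outer radius) over a half-disc plateau, with an
external shift emulating extrusion. Defaults approximate an adult medial
compartment: outer radius 22 mm, inner 9 mm, 170° arc, 6 mm peripheral
height, 22 mm plateau radius, 3 mm shift. It is a geometric idealization,
not an anatomical model: its role is rasterization testing, comparing
measures at clinical spacing against the same continuous geometry
rasterized 4× finer on every axis. At DESS spacing the extrusion measures
agree with the fine-grid reference within 0.03-0.09 mm, mean height within
0.05 mm, volume within 0.2% and coverage within 2 percentage points. Mean
width is the exception: because width varies steeply near the arc tips,
the per-slice mean evaluated at 1.5 mm slice centres differs from the same
mean at 0.375 mm centres by ~0.5 mm before any in-plane error — the
per-slice-mean width is intrinsically slice-thickness-dependent for
C-shaped geometry, a genuine limitation of slice-wise averaging rather
than of the implementation.

The **cohort simulator** (`simulate_cohort()`) draws matched pairs whose
group moments follow the published summary statistics of the 37-pair
progressor / non-progressor sample (see `cohort_sim_defaults()`):
covariates, KLG/JSN frequencies, baseline and 12-month-change cartilage
thickness and minJSW, and the nine tabulated meniscus measures per
compartment. Choices where print is silent:

* **Distributional form** — normal per measure (only means and SDs are
  published), clipped at physical bounds (volumes, heights, widths ≥ 0;
  percentages in [0, 100]; WOMAC in [0, 20]) with the clipping rate
  reported as `truncation_rate`. Clipping visibly shifts the moments of
  the lateral extrusion area, whose normal fit places 14-21% of its mass
  below zero — a reminder that the published mean ± SD cannot fully pin
  down a bounded quantity.
* **Correlation structure** — only the published entire-vs-central
  correlations are constrained (0.93 / 0.88 for mean extrusion vs central
  5 / central slice; 0.84, 0.85, 0.73, 0.90 for coverage, volume, height,
  width vs central 5). The unobserved central5-central1 correlation is
  completed as the product of the two published ones (a single-factor
  structure, always positive semi-definite); all other cross-measure
  correlations default to zero.
* **Change correlation** — medial cartilage-thickness change and minJSW
  change are drawn with correlation 0.6: both track medial structural
  loss, so a moderate positive correlation is the realistic default. This
  value controls how often progressor-parameter draws satisfy both
  classification criteria jointly.
* **Matching by construction** — sex and KLG are shared within a pair and
  the control's height, BMI and WOMAC are the case's values plus a uniform
  perturbation within half the caliper, so simulated pairs always satisfy
  the default `match_spec()`. Central-window means for coverage, volume,
  height and width reuse the entire-meniscus means, since no separate
  central-window means are published.
* **Maximum height** is not tabulated in the published summaries; it is
  modelled as mean height plus a positive peak increment purely to keep
  the max ≥ mean invariant.

What passing simulation tests show — and what they do not: the simulator
reproduces published *moments and correlations* under normality with
clipping. It does not model segmentation error, anatomical shape
variation, skewness, or the joint distribution of the ten measures, so
agreement on simulated cohorts validates the statistical pipeline, not the
biology.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are chosen to make
Monte-Carlo error negligible relative to the tolerances: 100 random masks
up to 16³ for exact oracle equivalence, 5000 simulated pairs for
effect-size recovery (sampling SE of d ≈ 0.02), 10⁴ replicates for CI
coverage (SE ≈ 0.2%), 500 test-retest differences for SDC recovery, and
matching instances up to 8×8 for exhaustive comparison. All simulation
flows through a single integer seed.

Known limitations: anterior/posterior (sagittal) extrusion is out of scope
— coronal stacks cannot resolve it; meniscus tears and other damage are
not assessed; sub-voxel surface reconstruction is deliberately avoided in
favour of exactly testable integer-cell conventions; NIfTI is the only
supported mask container.
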