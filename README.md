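# menisq

Quantitative 3D meniscus morphometry and structural-progression analysis
for knee osteoarthritis research.

## What it does and for whom

Meniscus extrusion — displacement of the meniscus beyond the external
margin of the tibial plateau — is a candidate predictor of subsequent
structural progression of knee osteoarthritis. Imaging researchers who
segment menisci on coronal MRI need reproducible, voxel-exact measures of
meniscus position and morphology, a principled definition of "progressor",
and matched-comparison statistics. `menisq` provides that pipeline:

1. **Morphometry** — from a voxelized segmentation of one femorotibial
   compartment (solid meniscus mask + tibial plateau footprint, axes
   coronal-slice / inferior-superior / internal-external), it computes per
   compartment: extrusion area (%), mean and maximum signed extrusion
   distance (mm), mean extrusion over the central 5 slices and the central
   slice, tibial plateau coverage (%), mean width (mm), mean and maximum
   height (mm), and volume (ml). The per-slice signed extrusion is
   `(x_max_meniscus − x_max_plateau) · s_x`; aggregation uses only slices
   containing both structures, and negative values (margin internal to the
   plateau) are preserved.
2. **Progression** — smallest-detectable-change thresholds
   (SDC = 1.96 × SD of test-retest change differences; defaults 102 µm
   medial and 92 µm lateral cartilage thickness, 328 µm minimum joint
   space width) classify knees as progressor (both medial losses exceed
   threshold), non-progressor (no loss exceeds its threshold) or
   indeterminate; eligibility keeps Kellgren-Lawrence grades 2-3; 1:1
   matching (exact sex and KLG; ±3 cm height, ±5 kg/m² BMI, ±5 WOMAC
   pain) solves an optimal bipartite matching — maximum pairs first, then
   minimum caliper-normalized distance.
3. **Statistics** — paired-t mean differences with 95% CIs, pooled-SD
   Cohen's D `d = (x̄₁ − x̄₂)/√((s₁² + s₂²)/2)`, and Pearson correlation /
   r²% between entire-meniscus and central-slice measures.
4. **Synthetic data** — box phantoms with closed-form ground truth,
   C-shaped wedge phantoms with a fine-grid rasterization reference, and a
   cohort simulator whose defaults follow published 37-pair group summary
   statistics, so the entire pipeline runs and is tested without any
   clinical data.

## Worked example

A five-slice box phantom whose meniscus margin sits 0-4 cells beyond the
plateau margin (1 mm in-plane spacing):

```r
library(menisq)
ph <- make_box_phantom(box_phantom_spec(n_slices = 5, external_offset = 0:4,
                                        spacing = c(1.5, 0.37, 1.0)))
compute_all_measures(ph$seg)
#> <meniscus_measures>
#>         extrusion_area_pct          mean_extrusion_mm
#>                     20.000                      2.000
#>           max_extrusion_mm mean_extrusion_central5_mm
#>                      4.000                      2.000
#> mean_extrusion_central1_mm               coverage_pct
#>                      2.000                     40.000
#>              width_mean_mm             height_mean_mm
#>                     10.000                      2.220
#>              height_max_mm                  volume_ml
#>                      2.220                      0.166
```

Offsets 0-4 cells at 1 mm give mean extrusion 2 mm and maximum 4 mm; 20%
of the 50-cell meniscus footprint lies outside the plateau; the 6-voxel
height at 0.37 mm z-spacing is 2.22 mm. Every value equals the phantom's
closed form exactly.

A simulated study-sized matched cohort, compared like a results table:

```r
co <- simulate_cohort(n_pairs = 37, seed = 1)
pm <- cohort_paired_measures(co, "medial")
format_comparison_table(comparison_table(pm$cases, pm$controls))
#>                                measure mean_case sd_case ... cohens_d    p
#> 1                   Extrusion area (%)      31.5    11.3 ...     0.14 0.56
#> 2         Mean extrusion distance (mm)       2.3     1.0 ...    -0.02 0.94
#> 3         Max. extrusion distance (mm)       4.8     1.4 ...     0.62 0.02
#> 4 Mean extrusion 5 central slices (mm)       3.0     1.3 ...     0.22 0.36
#> 5    Mean extrusion central slice (mm)       3.2     1.6 ...     0.40 0.08
#> 6          Tibial plateau coverage (%)      37.0    12.6 ...     0.09 0.74
#> 7                Width mean total (mm)       8.3     1.6 ...    -0.09 0.70
#> 8                     Height mean (mm)       2.8     0.4 ...     0.51 0.03
#> 9                          Volume (ml)       1.8     0.9 ...     0.27 0.24
```

At n = 37 the effect-size estimates are noisy (sampling SE of d at this
size is ≈ 0.24); the maximum-extrusion and height contrasts stand out, as
their generating parameters intend. Correlations between entire-meniscus
and central-window measures come from `correlation_table()`; at this
sample size the mean-extrusion entire-vs-central-5 correlation is r = 0.91
(82% variance explained) against a generating value of 0.93.

Mask files round-trip through NIfTI label volumes
(`write_segmented_compartment()` / `read_segmented_compartment()`), and a
thin command-line wrapper with `measure`, `classify`, `match`, `compare`,
`correlate` and `simulate` subcommands lives at `inst/scripts/menisq`.

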