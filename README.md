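# ecvatlas

Quantitative mapping of myocardial extracellular volume (ECV) from
late-enhancement iodine CT, with high-resolution **atlas maps** for focal
lesion detection.

## The problem

Late-enhancement CT with spectral iodine quantification can measure
myocardial ECV voxelwise:

```
ECV = (1 - hct) * I_myo / I_blood
```

where `hct` is the hematocrit (L/L) and `I` are iodine concentrations
(mg/mL) in myocardium and blood pool.  Elevated ECV marks fibrosis,
infarct, and edema — useful, for example, when assessing myocardial
injury after spontaneous coronary artery dissection, where gadolinium MRI
is the usual reference.  The catch is noise: at ~0.4 × 0.4 × 1.0 mm
sampling, iodine images are photon-starved, so single voxels are
unreliable even though well over 500,000 myocardial voxels are available.

This package implements the full pipeline that solves this by averaging
over anatomical compartments:

* **ECV computation** from iodine volumes, blood-pool reference (scalar
  or aortic ROI) and hematocrit, plus aortic SNR.
* **Raytraced compartmentalisation** of the left-ventricular wall from
  the long axis into 3 transmural depth layers × 34 short-axis layers ×
  72 angular sectors (≈ 2 × 2 mm cells on the surface; CSV export of all
  7344 cell means and voxel counts), and the standard AHA 16-segment,
  two-band polar aggregation.
* **Atlas maps**: each depth layer as a 34 × 72 matrix cut open
  anteriorly, denoised by 5 × 5 median filtration (reduces Gaussian
  noise about fourfold; a 3 × 3 filter manages just over twofold), then
  thresholded at 45 / 40 / 35 % ECV as markers of descending lesion
  probability, with per-layer volume percentages, absolute scar volume,
  and PDF renderings (bullseye polar maps and stacked atlas panels).
* **Pathologic-segment classification** per segment and band
  (subendo-/subepicardium) by three automated criteria — overlay
  (voxel clusters > 45 % ECV), polar (> 50 % of the segment above 45 %),
  atlas (> 25 % above 40 % after filtering) — merged by OR, with
  optional externally supplied visual reads.
* **Agreement statistics**: Cohen's weighted κ with interpretation bins,
  total/partial/no concordance, Wilcoxon signed-rank, median/IQR.
* A **synthetic LV phantom** (half-capsule shell, controllable lesions,
  MVO cores, Gaussian noise, exact ground-truth masks) so the entire
  chain is testable without patient data.

## Worked example

Simulate an infarct-like transmural lesion (55 % ECV, 30° wide) in an
otherwise normal ventricle (background 27 % ECV, hematocrit 0.40, blood
iodine 5 mg/mL, mild noise), recover ECV, and read the maps:

```r
library(ecvatlas)

les  <- lesion_spec(center_z = 15, center_theta = 0, angular_extent = 30,
                    longitudinal_extent = 30, transmural_range = c(0.1, 0.9),
                    lesion_ecv = 0.55)
spec <- phantom_spec(voxel_spacing = c(0.8, 0.8, 1), lesions = list(les),
                     noise_sigma = 0.4, seed = 42)
ph   <- generate_phantom(spec)

ecv  <- compute_ecv(iodine_study(ph$iodine, 5.0, 0.40))
grid <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
atlas <- build_atlas(grid)
atlas
#> <atlas_map> 3 depth layers, 34 x 72 cells, 5x5 median filter
#>   layer 1: % volume above 35/40/45 = 4.1/4.1/3.8
#>   layer 2: % volume above 35/40/45 = 3.6/3.6/3.4
#>   layer 3: % volume above 35/40/45 = 3.5/3.5/3.2

scar_volume(atlas, grid, 45)
#> [1] 2264.525

calls <- classify_segments(ecv, ph$truth$myocardium_mask, ph$truth$geometry,
                           grid = grid, atlas = atlas)
subset(as.data.frame(calls), pathologic,
       select = c(segment, band, criteria, atlas_fraction))
#>    segment    band            criteria atlas_fraction
#> 1        1 subendo overlay,polar,atlas      0.5061728
#> 2        1  subepi       overlay,atlas      0.4982079
#> 13       7 subendo             overlay      0.1282139
#> 14       7  subepi             overlay      0.1237668

which(segments_affected(calls))
#>  1  7
#>  1 13
```

The similar per-layer volume percentages (≈ 4 %) reflect the lesion's
transmurality; the lesion is called in basal anterior (segment 1, both
bands) and reaches into mid anterior (segment 7) where only the
voxelwise overlay criterion fires.  `render_atlas(atlas, "atlas.pdf")`
and `render_polar(aha16_aggregate(ecv, ph$truth$myocardium_mask,
ph$truth$geometry), "polar.pdf")` write the graphical maps;
`compartments_to_csv(grid, "compartments.csv")` exports the raw cells.

A YAML-driven end-to-end run (phantom → ECV → compartments → maps →
calls → agreement) is available as `run_pipeline(config, out_dir)` or
from the shell via `inst/cli/ecv-atlas.R
simulate|ecv|atlas|classify|agree|noise-sim|run`.

Per-patient pathologic-segment counts from an acute-phase (n = 16) and a
follow-up (n = 8) reading session (late-enhancement CT, LGE MRI, MRI
edema) ship as CSV fixtures — see `segment_counts_path()` — for the
summary and agreement statistics.

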