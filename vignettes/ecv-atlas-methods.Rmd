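---
title: "ECV atlas maps: model, sampling geometry, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECV atlas maps: model, sampling geometry, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvatlas)
```

## The measurement model

Late-enhancement CT with spectral iodine quantification measures, per
voxel, the iodine concentration in myocardium and blood pool at
quasi-equilibrium.  Because contrast media distributes in the
extracellular space, the myocardial extracellular volume fraction follows
from the concentration ratio corrected for the cellular fraction of
blood:

$$\mathrm{ECV} \;=\; (1 - \mathrm{hct}) \cdot
  \frac{I_\mathrm{myo}}{I_\mathrm{blood}},$$

with hematocrit in L/L and iodine concentrations in mg/mL.  `compute_ecv()`
applies this voxelwise; the blood-pool reference is a scalar or the mean
over an aortic ROI, fixed per study.  ECV is stored internally as a
fraction and displayed or thresholded in percent; keeping one internal
unit avoids threshold mix-ups.  Noise can drive individual voxels outside
$[0, 1]$: those are **counted** and clipped only for display, while
compartment averaging uses unclipped values — clipping before averaging
would bias low-signal regions upward.

Iodine maps at high spatial resolution are noisy (photon statistics), so
the package's central idea is to average ECV over anatomical compartments
that are large enough to suppress noise but small enough not to blur
focal lesions.

## Sampling geometry

All sampling uses a left-ventricular frame: a long axis from the centre
of the base to the apex tip, an anterior reference direction defining
azimuth 0, and endo-/epicardial surfaces expressed as radius functions of
axial position (analytic for the phantom, tabulated from a label mask
otherwise).  Fractional wall depth is measured along the radial ray from
the long axis: 0 at the endocardium, 1 at the epicardium.

Two compartmentalisations are built on this frame:

* **Atlas grid** — 34 short-axis layers (layer 1 at the base) × 72 angular
  sectors (sector 1 starting at the anterior cut, numbering in the AHA
  direction) × 3 transmural depth layers.  For a 7 cm long, 5 cm wide
  ventricle one cell spans about 2 × 2 mm on the epicardial surface.
  Each cell carries the arithmetic mean ECV and the voxel count of the
  voxels whose centres fall in it; `compartments_to_csv()` exports all
  3 × 34 × 72 = 7344 cells.
* **AHA-16 polar aggregation** — basal/mid/apical axial thirds split into
  6/6/4 segments, two transmural bands.

Analysis is restricted to fractional depths 0.10–0.90, excluding the
blood-pool and epicardial-fat partial-volume rims.  The two polar bands
are the inner (0.10–0.50) and outer (0.50–0.90) halves; the three atlas
depth layers are equal thirds of the same interval (0.10–0.367,
0.367–0.633, 0.633–0.90).  The three layers are named but their limits
are not prescribed anywhere authoritative; reusing the 10/90 margins
keeps both map types consistent, which is what the refinement-consistency
test asserts.

Voxels are assigned by **voxel-centre membership**, not by ray resampling
with interpolation: it is simpler, conservative, and exactly testable
(the partition property — every in-band voxel in exactly one cell — is
asserted by a brute-force loop).  "Raytracing" is thus interpreted as
radial geometric assignment.  Voxels within one in-plane voxel spacing of
the long axis have numerically unstable azimuth; they are discarded and
counted (`n_discarded_axis`).  Near the apex some cells can be empty:
they carry `NaN` mean and count 0 and are excluded from all percentages.
Indices are 1-based in every export and in the documentation.

## Median filtration and thresholds

Each depth layer is a 34 × 72 matrix, cut open at the anterior azimuth.
Speckle noise is removed with 5 × 5 **median** filtration
(`median_filter_matrix()`): medians suppress isolated outliers without
blurring edges, so lesions of about 1 cm surface diameter (≥ 5 × 5
cells) keep their core values exactly.  Boundary policy: the angular
dimension wraps circularly — the cut position is arbitrary, and the
wrap makes filtering commute exactly with rotating the cut, which is
tested — while longitudinal edges replicate.  Empty (`NaN`) cells are
excluded from each window's median so apex rows do not poison their
neighbourhoods.

For an i.i.d. Gaussian field the sample median of $n = k^2$ values has
asymptotic variance $\pi \sigma^2 / (2n)$, so a $k \times k$ median
filter reduces noise standard deviation by about $\sqrt{2k^2/\pi}$:
3.99 for 5 × 5 and 2.39 for 3 × 3.  `simulate_filter_noise_reduction()`
verifies this by direct simulation (interior cells only, to avoid edge
bias); the acceptance suite runs it at $10^6$ cells.

The filtered matrices are thresholded at 45, 40 and 35 % ECV — markers of
descending probability of a focal lesion (values below 30 % are most
likely normal, values above 50 % almost certainly pathologic).
Thresholds use strict `>` on full-precision values.  Per layer, the
volume percentage above each threshold is **voxel-count weighted**
(cells carry unequal voxel counts), and `scar_volume()` converts
supra-threshold cell counts into mm³.  Because sampling covers the
10–90 % depth band, reported scar volumes refer to that band.

## Pathologic-segment classification

`classify_segments()` evaluates three automated criteria per AHA
segment-band (16 segments × subendo/subepi = 32 calls), combined by OR:

1. **overlay** — a 6-connected cluster of ≥ 50 voxels (~10 mm³ at default
   spacing; configurable) with voxelwise ECV > 45 % inside the
   segment-band.  The published criterion ("areas with ECV elevation
   >45 % in overlay images") has no size floor; the cluster floor
   prevents single-voxel noise triggers.
2. **polar** — more than 50 % of the segment-band's voxels lie in
   *unfiltered* 34 × 72 cells (two matched depth bands) with mean
   ECV > 45 %.  Polar-type displays are unfiltered, hence the higher
   threshold.
3. **atlas** — more than 25 % of the segment-band's voxels lie in
   *filtered* atlas cells with ECV > 40 % (lower threshold because
   filtering smooths peaks).  The three atlas depth layers are
   apportioned onto the two bands with the midwall weighted half into
   each (`midwall = "split"`; `"both"` is available).  A consequence of
   the split is that a lesion confined strictly to the inner third
   registers a smaller fraction than its angular extent suggests; a
   lesion covering the subendocardial call band (inner half) measures
   faithfully.

Visual hyperenhancement reading of the late-enhancement images is human
interpretation and cannot be computed; external reads can be supplied as
a 32-vector and are merged by OR.  Fractions are voxel-volume weighted
throughout (whether the original readers judged polar fractions by
rendered area or by volume is not stated; volume is the defensible
automated choice).  Classification is monotone: raising any voxel's ECV
never turns a positive call negative (tested).

## Agreement statistics

`cohens_kappa()` implements weighted κ (linear weights by default; for
binary calls all schemes coincide, so the unspecified weighting of the
original analysis is immaterial) with the interpretation bins <0.20 no
agreement, 0.20–0.39 minimal, 0.40–0.59 weak, 0.60–0.79 moderate,
0.80–0.89 strong, 0.89–1.00 almost perfect; values in [0.89, 0.90) bin
as almost perfect, matching how published values at that boundary are
labelled.  κ is undefined when both raters are constant and identical;
this returns `NA` with a warning rather than a number.
`concordance_category()` implements the total/partial/none taxonomy
(two empty sets are vacuously total).  `wilcoxon_signed_rank()` drops
zero differences (classic policy), uses the exact distribution for
n ≤ 25 without ties and the tie-corrected normal approximation
otherwise.  `median_iqr()` reports the order-statistic midpoint;
quartiles default to linear interpolation (type 7) and are
convention-dependent — the bundled per-patient counts reproduce the
published medians but not all published IQRs under any standard
convention, so only medians are asserted.  Pooled κ treats all segments
across patients as exchangeable, which matches how single pooled values
are usually reported when per-patient dependence is negligible.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds the ground truth every downstream stage is
tested against: a **half-capsule** myocardial shell — a cylindrical
annulus closed by a hemispherical apex cap, open flat base — with
defaults of 70 mm length, 50 mm outer diameter, 10 mm wall, voxelized at
0.4 × 0.4 × 1.0 mm (about 514,000 myocardial voxels; the closed-form
shell volume $\pi (R_o^2 - R_i^2)(L - R_o) + \tfrac{2\pi}{3}(R_o^3 -
R_i^3)$ is the volume oracle).  The half-capsule is the simplest shape
with a well-defined long axis, an apex, and an analytic volume; any
smooth shell of the stated dimensions would serve, and users can
substitute label masks.  Background ECV defaults to 0.27 (inside the
normal band below 30 %), hematocrit to 0.40 L/L (a typical acute-phase
value), blood iodine to 5 mg/mL.  Lesions are wedges in
(azimuth × axial × depth) space with controllable ECV (typically
45–70 %), optional hypo-enhancing MVO cores, and exact voxel masks.
Gaussian noise on the iodine image emulates photon statistics;
generation is bit-reproducible under a fixed seed.

Not modelled: papillary muscles, trabeculation, the right ventricle,
realistic CT physics (beam hardening, spectral decomposition, detector
simulation), motion, and nonrigid registration — inputs are assumed
co-registered.  Passing tests on the phantom therefore demonstrate the
correctness of the sampling, filtering, thresholding and statistics, not
robustness to segmentation error or registration artifacts on patient
data.

## Numerical choices and problem sizes

* Membership and band edges use closed intervals at the outer limits
  (`depth == 0.9` belongs to the outermost band); ties at cell borders
  are resolved by `floor` on the continuous coordinate, so every voxel
  lands in exactly one cell.
* The noise-reduction simulation uses a ~1000 × 1000 matrix ($10^6$
  cells) in the acceptance suite — enough for the reduction factor's
  Monte-Carlo error to be well under the 0.1 assertion band — and
  smaller fields (~9 × 10⁴ cells) in the unit tests.
* Unit tests run the phantom at 1 × 1 × 2 mm or 0.8 × 0.8 × 1.0 mm
  spacing (tens of thousands to ~10⁵ myocardial voxels), which keeps the
  full suite under a minute while leaving every geometric effect
  resolvable; the acceptance suite generates the full-resolution default
  phantom where the claim concerns it.
* Rendered PDFs embed no varying timestamps (date digits are zeroed in
  place after rendering), making outputs byte-stable for fixed inputs.

## Known limitations

* The midwall apportioning in the atlas criterion is a modelling choice;
  with `midwall = "both"` calls become slightly more sensitive and less
  specific.
* Scar volumes are reported for the sampled 10–90 % depth band and are
  cell-quantised: lesions much smaller than a few cells are rounded away
  by design (that is what the median filter is for).
* Mask-derived geometry estimates surfaces from voxel-centre extrema per
  (axial, azimuthal) bin; near the apex cap these estimates are coarse,
  and the horizontal-ray depth convention degenerates at the apex tip
  (near-axis voxels are discarded).
* MVO cores are generated and rendered but deliberately not detected:
  hypo-enhancing cores sit below every ECV threshold, so atlas-style
  thresholding misses them by construction.
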