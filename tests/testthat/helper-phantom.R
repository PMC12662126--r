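# Shared fixture builders.  Coarse voxel spacings keep the suite fast; the
# acceptance tests use the full-resolution defaults where the claim under
# test requires them.

coarse_spec <- function(..., voxel_spacing = c(1, 1, 2)) {
  phantom_spec(..., voxel_spacing = voxel_spacing)
}

# spacing fine enough for voxel-cluster and fraction tests, still quick
medium_spacing <- c(0.8, 0.8, 1.0)

# noise level giving approximately `cell_pct` percent ECV noise on an
# unfiltered atlas cell mean, derived from the voxels-per-cell of the grid
sigma_for_cell_noise <- function(spec, cell_pct = 4, n_cells = 7344) {
  ph <- generate_phantom(spec)
  n_vox <- sum(ph$truth$myocardium_mask$values != 0)
  vox_per_cell <- n_vox * 0.8 / n_cells       # ~80% of voxels are in band
  sigma_ecv <- cell_pct / 100 * sqrt(vox_per_cell)
  sigma_ecv * spec$blood_iodine / (1 - spec$hematocrit)
}

phantom_ecv <- function(ph) {
  compute_ecv(iodine_study(ph$iodine, ph$spec$blood_iodine, ph$spec$hematocrit))
}
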