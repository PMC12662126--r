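#' Specification of a synthetic LV phantom
#'
#' The phantom myocardium is a half-capsule shell: a cylindrical annulus of
#' length `lv_length - outer_diameter / 2` closed by a hemispherical apex
#' cap, with an open flat base perpendicular to the long axis.  The long
#' axis runs along +z from the base plane at z = 0 to the apex tip at
#' z = `lv_length`; the anterior reference (azimuth 0, centre of AHA
#' segment 1) is +x.  Ground-truth ECV is `background_ecv` everywhere in
#' the myocardium except inside lesions; the iodine concentration of a
#' myocardial voxel is `ecv * blood_iodine / (1 - hematocrit)` plus
#' optional Gaussian noise.
#'
#' Defaults give a heart of 7 cm height and 5 cm outer diameter with a
#' 1 cm wall, voxelized at 0.4 x 0.4 x 1.0 mm, background ECV 0.27 (inside
#' the normal range, below 30%), hematocrit 0.40 L/L and a blood-pool
#' iodine concentration of 5 mg/mL.
#'
#' @param lv_length Base-to-apex length in mm.
#' @param outer_diameter Outer (epicardial) diameter in mm.
#' @param wall_thickness Myocardial wall thickness in mm; must be smaller
#'   than `outer_diameter / 2`.
#' @param voxel_spacing Voxel spacing in mm (x, y, z).
#' @param background_ecv Normal-myocardium ECV fraction in (0, 1).
#' @param hematocrit Hematocrit in L/L, in (0, 1).
#' @param blood_iodine Blood-pool iodine concentration in mg/mL.
#' @param noise_sigma Std. dev. of additive Gaussian noise on the iodine
#'   image, mg/mL (0 = noiseless).
#' @param lesions List of [lesion_spec()] objects.
#' @param aorta If `TRUE`, add a cylindrical blood-filled "aorta" insert
#'   beside the LV (used for signal-to-noise measurements).
#' @param seed Integer seed making noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv_length = 70, outer_diameter = 50,
                         wall_thickness = 10,
                         voxel_spacing = c(0.4, 0.4, 1.0),
                         background_ecv = 0.27, hematocrit = 0.40,
                         blood_iodine = 5.0, noise_sigma = 0,
                         lesions = list(), aorta = FALSE, seed = 1L) {
  voxel_spacing <- as.numeric(unlist(voxel_spacing))
  if (length(voxel_spacing) != 3L) stop("voxel_spacing must have 3 entries")
  if (wall_thickness >= outer_diameter / 2)
    stop("wall_thickness must be < outer_diameter / 2")
  if (background_ecv <= 0 || background_ecv >= 1)
    stop("background_ecv must be in (0, 1)")
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be in (0, 1)")
  if (any(voxel_spacing <= 0)) stop("voxel spacings must be positive")
  if (blood_iodine <= 0) stop("blood_iodine must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (lv_length <= outer_diameter / 2)
    stop("lv_length must exceed the apex cap radius (outer_diameter / 2)")
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  structure(list(lv_length = lv_length, outer_diameter = outer_diameter,
                 wall_thickness = wall_thickness,
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_ecv = background_ecv, hematocrit = hematocrit,
                 blood_iodine = blood_iodine, noise_sigma = noise_sigma,
                 lesions = lesions, aorta = isTRUE(aorta),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of a focal lesion
#'
#' A lesion is a wedge of the myocardial wall: an azimuthal range around a
#' centre angle, an axial (longitudinal) range around a centre height, and
#' a transmural fractional-depth range.  Its centre can be given either as
#' atlas indices (`layer` in 1..34 from the base, `sector` in 1..72 from
#' the anterior cut) or directly as `center_z` (mm from the base) and
#' `center_theta` (degrees).  An optional `mvo_core` (itself a
#' `lesion_spec` with `lesion_ecv` below background, strictly inside the
#' parent) models a microvascular-obstruction core of diminished
#' perfusion.
#'
#' @param layer,sector Atlas-grid centre indices (alternative to
#'   `center_z`/`center_theta`).
#' @param center_z,center_theta Explicit centre: axial mm / azimuth
#'   degrees.
#' @param angular_extent Azimuthal width in degrees.
#' @param longitudinal_extent Axial length in mm.
#' @param transmural_range Fractional depth interval `(start, end)` with
#'   `0 <= start < end <= 1` (0 = endocardium).
#' @param lesion_ecv ECV fraction inside the lesion, in (0, 1].
#' @param mvo_core Optional nested `lesion_spec`.
#' @param name Label used in error messages.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(layer = NULL, sector = NULL, center_z = NULL,
                        center_theta = NULL, angular_extent = 30,
                        longitudinal_extent = 15,
                        transmural_range = c(0, 1), lesion_ecv = 0.55,
                        mvo_core = NULL, name = "lesion") {
  transmural_range <- as.numeric(unlist(transmural_range))
  if (is.null(center_z) && is.null(layer))
    stop("give either (layer, sector) or (center_z, center_theta)")
  if (lesion_ecv <= 0 || lesion_ecv > 1)
    stop("lesion_ecv must be in (0, 1]")
  if (length(transmural_range) != 2L ||
      transmural_range[1] >= transmural_range[2] ||
      transmural_range[1] < 0 || transmural_range[2] > 1)
    stop("transmural_range must be an ordered pair within [0, 1]")
  if (!is.null(mvo_core) && !inherits(mvo_core, "lesion_spec"))
    stop("mvo_core must be a lesion_spec")
  structure(list(layer = layer, sector = sector, center_z = center_z,
                 center_theta = center_theta,
                 angular_extent = angular_extent,
                 longitudinal_extent = longitudinal_extent,
                 transmural_range = as.numeric(transmural_range),
                 lesion_ecv = lesion_ecv, mvo_core = mvo_core,
                 name = name),
            class = "lesion_spec")
}

lesion_center <- function(lesion, lv_length, n_layers = 34, n_sectors = 72) {
  if (!is.null(lesion$center_z)) {
    list(z = lesion$center_z, theta = lesion$center_theta %% 360)
  } else {
    list(z = (lesion$layer - 0.5) / n_layers * lv_length,
         theta = ((lesion$sector - 0.5) / n_sectors * 360) %% 360)
  }
}

# logical array marking a lesion wedge, given precomputed cylindrical
# coordinates and depths of all voxels
lesion_region <- function(lesion, co, depth, inside, lv_length) {
  cen <- lesion_center(lesion, lv_length)
  dtheta <- (co$theta - cen$theta + 180) %% 360 - 180
  inside &
    abs(dtheta) <= lesion$angular_extent / 2 &
    abs(co$z - cen$z) <= lesion$longitudinal_extent / 2 &
    depth >= lesion$transmural_range[1] &
    depth <= lesion$transmural_range[2]
}

#' Generate a synthetic LV iodine phantom
#'
#' Builds the half-capsule myocardial shell described by `spec` on a
#' regular voxel grid (membership by voxel-centre inclusion between the
#' endo- and epicardial surfaces), paints ground-truth ECV (background
#' plus lesions and MVO cores), converts ECV to a late-enhancement iodine
#' concentration via `iodine = ecv * blood_iodine / (1 - hematocrit)`,
#' fills the ventricular cavity (and optional aorta insert) with blood
#' iodine, and adds Gaussian noise if requested.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `iodine` (the noisy iodine [voxel_volume()]) and
#'   `truth`: `ecv` (noiseless ECV fractions), `myocardium_mask`,
#'   `lesion_mask`, optional `aorta_mask`, and `geometry`
#'   (an analytic [lv_geometry()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  Ro <- spec$outer_diameter / 2
  Ri <- Ro - spec$wall_thickness
  L <- spec$lv_length
  Lc <- L - Ro                      # cylindrical part, then hemispherical cap
  sp <- spec$voxel_spacing
  margin <- 2 * sp
  xr <- Ro + margin[1]
  if (spec$aorta) xr <- Ro + 2 * 10 + 8   # room for the aorta insert at +x
  nx <- 2L * as.integer(ceiling(xr / sp[1])) + 1L
  ny <- 2L * as.integer(ceiling((Ro + margin[2]) / sp[2])) + 1L
  nz <- as.integer(ceiling((L + 2 * margin[3]) / sp[3])) + 1L
  origin <- c(-(nx - 1) / 2 * sp[1], -(ny - 1) / 2 * sp[2],
              -margin[3] + sp[3] / 2)
  vol <- voxel_volume(array(0, dim = c(nx, ny, nz)), spacing = sp,
                      origin = origin)
  ctr <- voxel_centers(vol)
  x <- ctr$x; y <- ctr$y; z <- ctr$z
  r <- sqrt(x^2 + y^2)

  r_endo <- function(zz) ifelse(zz <= Lc, Ri,
                                sqrt(pmax(Ri^2 - (zz - Lc)^2, 0)))
  r_epi <- function(zz) ifelse(zz <= Lc, Ro,
                               sqrt(pmax(Ro^2 - (zz - Lc)^2, 0)))
  geometry <- lv_geometry(axis_point = c(0, 0, 0), long_axis = c(0, 0, 1),
                          anterior = c(1, 0, 0), length = L,
                          r_endo = r_endo, r_epi = r_epi,
                          type = "analytic")

  re <- r_endo(z); rp <- r_epi(z)
  in_z <- z >= 0 & z <= L
  myo <- in_z & r >= re & r <= rp & rp > re
  cavity <- in_z & r < re & z <= Lc + Ri

  thick <- rp - re
  depth <- ifelse(myo, (r - re) / thick, NA_real_)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  co <- list(z = z, theta = theta)

  ecv <- array(0, dim = dim(vol$values))
  ecv[myo] <- spec$background_ecv
  lesion_mask <- array(FALSE, dim = dim(vol$values))
  for (les in spec$lesions) {
    reg <- lesion_region(les, co, depth, myo, L)
    if (!any(reg))
      stop(sprintf("lesion '%s' lies outside the myocardial shell", les$name))
    ecv[reg] <- les$lesion_ecv
    lesion_mask <- lesion_mask | reg
    if (!is.null(les$mvo_core)) {
      core <- lesion_region(les$mvo_core, co, depth, myo, L)
      if (!any(core))
        stop(sprintf("MVO core of lesion '%s' lies outside the myocardial shell",
                     les$name))
      if (any(core & !reg))
        stop(sprintf("MVO core of lesion '%s' extends outside its parent lesion",
                     les$name))
      ecv[core] <- les$mvo_core$lesion_ecv
      lesion_mask <- lesion_mask | core
    }
  }

  iodine <- array(0, dim = dim(vol$values))
  iodine[myo] <- ecv[myo] * spec$blood_iodine / (1 - spec$hematocrit)
  iodine[cavity] <- spec$blood_iodine

  aorta_mask <- NULL
  if (spec$aorta) {
    acx <- Ro + 18                      # centre of the 10 mm-radius insert
    aorta <- (x - acx)^2 + y^2 <= 10^2 & in_z
    iodine[aorta] <- spec$blood_iodine
    aorta_mask <- new_volume_like(vol, array(as.integer(aorta), dim = dim(vol$values)))
  }

  iod_vol <- new_volume_like(vol, iodine)
  if (spec$noise_sigma > 0)
    iod_vol <- add_noise(iod_vol, spec$noise_sigma, seed = spec$seed)

  truth <- list(ecv = new_volume_like(vol, ecv),
                myocardium_mask = new_volume_like(vol, array(as.integer(myo), dim = dim(vol$values))),
                lesion_mask = new_volume_like(vol, array(as.integer(lesion_mask), dim = dim(vol$values))),
                geometry = geometry)
  if (!is.null(aorta_mask)) truth$aorta_mask <- aorta_mask
  list(iodine = iod_vol, truth = truth, spec = spec)
}

#' Add Gaussian noise to a volume
#'
#' Independent additive N(0, sigma^2) noise on every voxel, emulating the
#' random statistical fluctuations of measured photons in iodine images.
#' Deterministic under a fixed seed; the caller's RNG state is restored.
#'
#' @param volume A [voxel_volume()].
#' @param sigma Noise standard deviation (same units as the volume).
#' @param seed Integer seed.
#' @return A new [voxel_volume()].
#' @export
add_noise <- function(volume, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(volume)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  noisy <- volume$values + array(stats::rnorm(length(volume$values), 0, sigma),
                                 dim = dim(volume$values))
  new_volume_like(volume, noisy)
}

#' Closed-form myocardial shell volume of a phantom
#'
#' Cylinder annulus plus hemispherical shell:
#' `pi (Ro^2 - Ri^2) (L - Ro) + (2 pi / 3)(Ro^3 - Ri^3)` in mm^3.  Used as
#' the analytic oracle for voxelized shell volumes.
#'
#' @param spec A [phantom_spec()].
#' @return Volume in mm^3.
#' @export
shell_volume_mm3 <- function(spec) {
  Ro <- spec$outer_diameter / 2
  Ri <- Ro - spec$wall_thickness
  pi * (Ro^2 - Ri^2) * (spec$lv_length - Ro) + 2 * pi / 3 * (Ro^3 - Ri^3)
}
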