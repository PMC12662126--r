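#' Bundle an iodine study
#'
#' The raw input of ECV computation: a late-enhancement iodine
#' concentration volume, a blood-pool iodine reference (either a scalar in
#' mg/mL or an aortic ROI mask over the iodine volume, whose mean is
#' used), and the patient hematocrit.
#'
#' @param iodine_volume A [voxel_volume()] of iodine concentrations
#'   (mg/mL).
#' @param blood_iodine Scalar blood-pool iodine (mg/mL), or a
#'   [voxel_volume()] ROI mask (non-zero = blood pool).
#' @param hematocrit Hematocrit fraction (L/L), in (0, 1).
#' @return An object of class `iodine_study`.
#' @export
iodine_study <- function(iodine_volume, blood_iodine, hematocrit) {
  stopifnot(inherits(iodine_volume, "voxel_volume"))
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be in (0, 1)")
  if (inherits(blood_iodine, "voxel_volume")) {
    stopifnot_same_grid(iodine_volume, blood_iodine, "iodine volume and blood ROI")
    if (!any(blood_iodine$values != 0)) stop("blood-pool ROI mask is empty")
  } else {
    blood_iodine <- as.numeric(blood_iodine)
    if (length(blood_iodine) != 1L || !is.finite(blood_iodine) || blood_iodine <= 0)
      stop("scalar blood_iodine must be a single positive number (mg/mL)")
  }
  structure(list(iodine_volume = iodine_volume, blood_iodine = blood_iodine,
                 hematocrit = hematocrit),
            class = "iodine_study")
}

#' Voxelwise extracellular volume fraction
#'
#' Computes `ECV = (1 - hematocrit) * iodine_myocardium / iodine_blood`
#' for every voxel.  The blood-pool denominator is fixed per study: the
#' scalar reference, or the mean over the aortic ROI.  Values are stored
#' as fractions and left unclipped so that downstream compartment means
#' remain unbiased; the counts of voxels below 0 and above 1 are recorded,
#' and [clip_ecv()] produces a \[0, 1\]-clipped copy for display and
#' voxelwise thresholding.  `NaN` iodine voxels propagate to `NaN` ECV.
#'
#' @param study An [iodine_study()].
#' @return An object of class `ecv_volume`: `volume` (the unclipped
#'   fraction [voxel_volume()]), `blood_iodine` (denominator used),
#'   `hematocrit`, `n_below_0`, `n_above_1`.
#' @export
compute_ecv <- function(study) {
  stopifnot(inherits(study, "iodine_study"))
  blood <- if (inherits(study$blood_iodine, "voxel_volume")) {
    roi <- study$blood_iodine$values != 0
    mean(study$iodine_volume$values[roi])
  } else study$blood_iodine
  if (!is.finite(blood) || blood <= 0)
    stop("blood-pool iodine mean must be positive")
  vals <- (1 - study$hematocrit) * study$iodine_volume$values / blood
  structure(list(volume = new_volume_like(study$iodine_volume, vals),
                 blood_iodine = blood, hematocrit = study$hematocrit,
                 n_below_0 = sum(vals < 0, na.rm = TRUE),
                 n_above_1 = sum(vals > 1, na.rm = TRUE)),
            class = "ecv_volume")
}

#' @export
print.ecv_volume <- function(x, ...) {
  cat(sprintf("<ecv_volume> blood iodine %.3f mg/mL, hct %.2f; %d voxels < 0, %d > 1\n",
              x$blood_iodine, x$hematocrit, x$n_below_0, x$n_above_1))
  print(x$volume)
  invisible(x)
}

#' Clip an ECV volume to the physical range
#'
#' Returns a copy with values clipped to \[0, 1\] for rendering and
#' voxelwise thresholding.  Compartment averaging uses the unclipped
#' values.
#'
#' @param ecv An `ecv_volume`.
#' @return A [voxel_volume()] of clipped fractions.
#' @export
clip_ecv <- function(ecv) {
  stopifnot(inherits(ecv, "ecv_volume"))
  new_volume_like(ecv$volume, pmin(pmax(ecv$volume$values, 0), 1))
}

#' Signal-to-noise ratio of the aortic blood pool
#'
#' SNR of the late-enhancement iodine image: mean iodine value over the
#' aortic-lumen ROI divided by its standard deviation (denominator n - 1).
#' A constant ROI has zero standard deviation; this is signalled as an
#' infinite SNR with a warning rather than an error.
#'
#' @param iodine_volume A [voxel_volume()] of iodine concentrations.
#' @param aorta_roi ROI mask ([voxel_volume()] or logical/numeric array),
#'   non-zero = aortic lumen; at least 2 voxels.
#' @return Scalar SNR (possibly `Inf`).
#' @export
compute_snr <- function(iodine_volume, aorta_roi) {
  roi <- if (inherits(aorta_roi, "voxel_volume")) aorta_roi$values else aorta_roi
  vals <- iodine_volume$values[roi != 0]
  if (length(vals) < 2L) stop("aortic ROI must contain at least 2 voxels")
  s <- stats::sd(vals)
  if (s == 0) {
    warning("aortic ROI has zero variance; SNR is infinite")
    return(Inf)
  }
  mean(vals) / s
}
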