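#' Voxel volume container
#'
#' A minimal container for a scalar field on a regular, axis-aligned voxel
#' grid: a 3-D numeric array plus voxel spacing and world-space origin.
#' World coordinates follow `world = origin + (index - 1) * spacing` with
#' 1-based array indices, i.e. `origin` is the world position of the centre
#' of voxel `[1, 1, 1]`.
#'
#' @param values Numeric 3-D array.
#' @param spacing Numeric length-3 vector of voxel spacings in mm, all
#'   strictly positive.
#' @param origin Numeric length-3 vector, world position (mm) of the centre
#'   of the first voxel.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Volume of a single voxel in cubic millimetres
#' @param volume A `voxel_volume`.
#' @return Scalar, mm^3.
#' @export
voxel_mm3 <- function(volume) prod(volume$spacing)

#' World coordinates of every voxel centre
#'
#' @param volume A `voxel_volume`.
#' @return A list with numeric arrays `x`, `y`, `z` of the same dimensions
#'   as `volume$values` holding the world coordinate (mm) of each voxel
#'   centre.
#' @export
voxel_centers <- function(volume) {
  d <- dim(volume$values)
  ax <- lapply(1:3, function(k) volume$origin[k] + (seq_len(d[k]) - 1) * volume$spacing[k])
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), dim = d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), dim = d))
}

new_volume_like <- function(template, values) {
  voxel_volume(values, spacing = template$spacing, origin = template$origin)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}

#' Read a volume from a NIfTI-1 file
#'
#' The voxel grid must be axis-aligned: the rotation part of the NIfTI
#' affine must be diagonal (up to sign).  Spacing and origin are taken from
#' the affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("cannot read NIfTI file %s: %s",
                                                   path, conditionMessage(e))))
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))))
    stop(sprintf("non-axis-aligned affine in %s; only diagonal affines are supported", path))
  spacing <- abs(diag(rot))
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop(sprintf("%s is not a 3-D volume", path))
  arr <- array(as.double(arr), dim = dim(arr))   # drop niftiImage attributes
  voxel_volume(arr, spacing = spacing, origin = m[1:3, 4])
}

#' Write a volume to a NIfTI-1 file
#'
#' Spacing and origin are stored in the sform affine.  `datatype`
#' "float" (32-bit) is the default for scalar maps; use "uint8" for label
#' masks.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, e.g. "float" or "uint8".
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "float") {
  img <- RNifti::asNifti(volume$values, datatype = datatype)
  aff <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
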