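#' Left-ventricular geometry
#'
#' The coordinate frame every sampling operation uses.  The LV long axis
#' runs from the centre of the open base towards the apex; axial position
#' `z` is measured in mm from the base plane (0) to the apex tip
#' (`length`).  The azimuth angle is measured about the long axis, starting
#' at `anterior` (the anterior cut, centre of AHA segment 1) and increasing
#' in the AHA numbering direction (anterior, anteroseptal, inferoseptal,
#' ...), i.e. counterclockwise about the long axis by the right-hand rule
#' with the thumb pointing base to apex.
#'
#' Endocardial and epicardial surfaces are described as radius functions of
#' axial position (`r_endo(z)`, `r_epi(z)`), either analytic (phantom) or
#' tabulated from a myocardium label mask (see [geometry_from_mask()]).
#'
#' @param axis_point World position (mm) of the centre of the base plane.
#' @param long_axis Unit vector of the long axis, pointing base to apex.
#' @param anterior Unit vector perpendicular to `long_axis` marking
#'   azimuth 0 (anterior).
#' @param length Base-to-apex extent in mm.
#' @param r_endo,r_epi Vectorised functions of axial position (mm from the
#'   base) returning the endo-/epicardial radius in mm.
#' @param type `"analytic"` or `"mask"`.
#' @return An object of class `lv_geometry`.
#' @export
lv_geometry <- function(axis_point, long_axis, anterior, length,
                        r_endo, r_epi, type = "analytic") {
  long_axis <- as.numeric(long_axis); anterior <- as.numeric(anterior)
  nrm <- sqrt(sum(long_axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("degenerate long axis (zero length)")
  long_axis <- long_axis / nrm
  na <- sqrt(sum(anterior^2))
  if (!is.finite(na) || na < 1e-12) stop("degenerate anterior reference vector")
  anterior <- anterior / na
  if (abs(sum(long_axis * anterior)) > 1e-8)
    stop("anterior reference must be perpendicular to the long axis")
  if (!is.numeric(length) || length <= 0) stop("length must be positive (mm)")
  structure(list(axis_point = as.numeric(axis_point), long_axis = long_axis,
                 anterior = anterior,
                 lateral = c(long_axis[2] * anterior[3] - long_axis[3] * anterior[2],
                             long_axis[3] * anterior[1] - long_axis[1] * anterior[3],
                             long_axis[1] * anterior[2] - long_axis[2] * anterior[1]),
                 length = length, r_endo = r_endo, r_epi = r_epi, type = type),
            class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf("<lv_geometry> %s, length %.1f mm, axis (%.2f, %.2f, %.2f)\n",
              x$type, x$length, x$long_axis[1], x$long_axis[2], x$long_axis[3]))
  invisible(x)
}

# Cylindrical coordinates of world points in the LV frame:
# z axial (mm from base), r radial distance from the long axis (mm),
# theta azimuth in degrees in [0, 360).
lv_coords <- function(geometry, pts) {
  pts <- matrix(pts, ncol = 3)
  d1 <- pts[, 1] - geometry$axis_point[1]
  d2 <- pts[, 2] - geometry$axis_point[2]
  d3 <- pts[, 3] - geometry$axis_point[3]
  z <- d1 * geometry$long_axis[1] + d2 * geometry$long_axis[2] + d3 * geometry$long_axis[3]
  u <- d1 * geometry$anterior[1] + d2 * geometry$anterior[2] + d3 * geometry$anterior[3]
  v <- d1 * geometry$lateral[1] + d2 * geometry$lateral[2] + d3 * geometry$lateral[3]
  theta <- atan2(v, u) * 180 / pi
  theta <- theta %% 360
  list(z = z, r = sqrt(u^2 + v^2), theta = theta)
}

#' Fractional wall depth of points in the myocardial wall
#'
#' Depth is measured along the radial ray from the long axis through the
#' point: 0 at the endocardial surface, 1 at the epicardial surface, linear
#' in the radius between the two surface radii at the point's axial
#' position.
#'
#' @param geometry An [lv_geometry()].
#' @param pts An n x 3 matrix (or length-3 vector) of world coordinates in
#'   mm.
#' @param strict If `TRUE` (default), points outside the myocardial shell
#'   (depth outside \[0, 1\] beyond a small tolerance, or outside the
#'   axial extent) raise an error; if `FALSE`, depths are returned
#'   unclamped.
#' @return Numeric vector of depths in \[0, 1\].
#' @export
wall_depth <- function(geometry, pts, strict = TRUE) {
  co <- lv_coords(geometry, pts)
  re <- geometry$r_endo(co$z)
  rp <- geometry$r_epi(co$z)
  thick <- rp - re
  bad_ax <- !is.finite(thick) | thick <= 0 | co$z < -1e-9 | co$z > geometry$length + 1e-9
  depth <- (co$r - re) / thick
  if (strict) {
    tol <- 1e-9
    if (any(bad_ax) || any(depth < -tol | depth > 1 + tol, na.rm = TRUE))
      stop("point(s) outside the myocardial shell")
    depth <- pmin(pmax(depth, 0), 1)
  }
  depth
}

#' Derive LV geometry from a myocardium label mask
#'
#' Endocardial and epicardial surface radii are tabulated from the mask:
#' voxel centres are binned by axial position (one bin per axial voxel
#' spacing) and azimuth (`n_sectors` bins), and the endo/epi radius of each
#' bin is the minimum/maximum voxel-centre radius it contains.  Surface
#' lookups fall back to the nearest non-empty azimuthal bin of the same
#' axial bin.
#'
#' @param mask A [voxel_volume()] with non-zero values marking myocardium.
#' @param long_axis,anterior Frame vectors (defaults: +z axis, +x
#'   anterior).
#' @param axis_point Optional base-plane centre; by default the in-plane
#'   centroid of the mask at the axial position of its first (most basal)
#'   occupied slice, with the base plane half a voxel below the most basal
#'   voxel centre.
#' @param n_sectors Azimuthal bins for the surface tables (default 72).
#' @return An [lv_geometry()] of type `"mask"`.
#' @export
geometry_from_mask <- function(mask, long_axis = c(0, 0, 1),
                               anterior = c(1, 0, 0), axis_point = NULL,
                               n_sectors = 72L) {
  sel <- which(mask$values != 0)
  if (length(sel) == 0L) stop("empty myocardium mask")
  ctr <- voxel_centers(mask)
  px <- ctr$x[sel]; py <- ctr$y[sel]; pz <- ctr$z[sel]
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  if (is.null(axis_point)) {
    # project voxel centres on the axis, take the basal-most slice
    zproj <- px * long_axis[1] + py * long_axis[2] + pz * long_axis[3]
    dz <- sum(mask$spacing * abs(long_axis))
    base_z <- min(zproj) - dz / 2
    cen <- c(mean(px), mean(py), mean(pz))
    cz <- sum(cen * long_axis)
    axis_point <- cen + (base_z - cz) * long_axis
  }
  geo0 <- lv_geometry(axis_point, long_axis, anterior, length = 1,
                      r_endo = function(z) rep(NA_real_, length(z)),
                      r_epi = function(z) rep(NA_real_, length(z)),
                      type = "mask")
  co <- lv_coords(geo0, cbind(px, py, pz))
  dz <- sum(mask$spacing * abs(geo0$long_axis))
  len <- max(co$z) + dz / 2
  nzb <- max(1L, as.integer(ceiling(len / dz)))
  zbin <- pmin(nzb, pmax(1L, 1L + floor(co$z / dz)))
  sbin <- pmin(n_sectors, 1L + floor(co$theta / 360 * n_sectors))
  key <- (zbin - 1L) * n_sectors + sbin
  re_tab <- rep(NA_real_, nzb * n_sectors)
  rp_tab <- rep(NA_real_, nzb * n_sectors)
  agg_min <- tapply(co$r, key, min)
  agg_max <- tapply(co$r, key, max)
  re_tab[as.integer(names(agg_min))] <- agg_min
  rp_tab[as.integer(names(agg_max))] <- agg_max
  lookup <- function(tab) {
    force(tab)
    function(z) {
      zb <- pmin(nzb, pmax(1L, 1L + floor(z / dz)))
      # no azimuth at lookup time: use the azimuth-median of the bin row
      vapply(zb, function(b) {
        row <- tab[((b - 1L) * n_sectors + 1L):(b * n_sectors)]
        if (all(is.na(row))) NA_real_ else stats::median(row, na.rm = TRUE)
      }, numeric(1))
    }
  }
  geo <- lv_geometry(axis_point, long_axis, anterior, length = len,
                     r_endo = lookup(re_tab), r_epi = lookup(rp_tab),
                     type = "mask")
  geo$surface_tables <- list(r_endo = matrix(re_tab, nrow = n_sectors),
                             r_epi = matrix(rp_tab, nrow = n_sectors),
                             dz = dz, n_sectors = n_sectors, n_zbins = nzb)
  geo
}

# depth for points against a mask geometry using the per-(zbin, sector)
# surface tables (more faithful than the azimuth-median fallback).
wall_depth_mask <- function(geometry, pts) {
  st <- geometry$surface_tables
  if (is.null(st)) stop("geometry has no surface tables; not mask-derived")
  co <- lv_coords(geometry, pts)
  zb <- pmin(st$n_zbins, pmax(1L, 1L + floor(co$z / st$dz)))
  sb <- pmin(st$n_sectors, 1L + floor(co$theta / 360 * st$n_sectors))
  re <- st$r_endo[cbind(sb, zb)]
  rp <- st$r_epi[cbind(sb, zb)]
  d <- (co$r - re) / (rp - re)
  d[is.finite(re) & is.finite(rp) & rp - re < 1e-9] <- 0.5   # single-voxel bin
  pmin(pmax(d, 0), 1)
}

band_index <- function(depth, n_bands, limits) {
  width <- (limits[2] - limits[1]) / n_bands
  pmin(n_bands, pmax(1L, 1L + as.integer(floor((depth - limits[1]) / width))))
}

#' Collect ECV voxels into atlas compartments
#'
#' Every myocardial voxel whose fractional wall depth lies within
#' `band_limits` is assigned, by its centre, to exactly one
#' (depth band, layer, sector) compartment: the layer by uniform
#' partition of the base-to-apex axial extent (layer 1 = base), the sector
#' by azimuth about the long axis (sector 1 starts at the anterior cut),
#' and the depth band by equal subdivision of the `band_limits` interval
#' (band 1 = subendocardial).  The compartment value is the arithmetic
#' mean of the unclipped ECV of its voxels.
#'
#' Voxels closer to the long axis than one in-plane voxel spacing have an
#' unstable azimuth and are discarded (their number is recorded in the
#' result).
#'
#' @param ecv An [ecv_volume()] or [voxel_volume()] of ECV fractions.
#' @param mask Myocardium mask ([voxel_volume()], non-zero = myocardium).
#' @param geometry An [lv_geometry()].
#' @param n_layers,n_sectors Grid dimensions (defaults 34 and 72).
#' @param depth_bands Number of transmural bands (default 3:
#'   subendocardium, midwall, subepicardium).
#' @param band_limits Fractional wall-depth interval analysed (default
#'   0.10–0.90, excluding blood-pool and epicardial partial-volume rims).
#' @return A `compartment_grid`: arrays `mean_ecv` and `voxel_count` of
#'   dimension `c(depth_bands, n_layers, n_sectors)` plus sampling
#'   metadata.
#' @export
build_compartments <- function(ecv, mask, geometry, n_layers = 34L,
                               n_sectors = 72L, depth_bands = 3L,
                               band_limits = c(0.10, 0.90)) {
  ev <- if (inherits(ecv, "ecv_volume")) ecv$volume else ecv
  stopifnot_same_grid(ev, mask, "ECV and mask")
  sel <- which(mask$values != 0)
  if (length(sel) == 0L) stop("empty myocardium mask")
  ctr <- voxel_centers(mask)
  pts <- cbind(ctr$x[sel], ctr$y[sel], ctr$z[sel])
  co <- lv_coords(geometry, pts)
  r_min <- min(mask$spacing[1:2])
  on_axis <- co$r < r_min
  if (geometry$type == "mask") {
    depth <- wall_depth_mask(geometry, pts)
  } else {
    depth <- wall_depth(geometry, pts, strict = FALSE)
  }
  in_band <- !on_axis & is.finite(depth) &
    depth >= band_limits[1] & depth <= band_limits[2] &
    co$z >= 0 & co$z <= geometry$length
  vals <- ev$values[sel][in_band]
  layer <- pmin(n_layers, pmax(1L, 1L + as.integer(floor(co$z[in_band] / geometry$length * n_layers))))
  sector <- pmin(n_sectors, 1L + as.integer(floor(co$theta[in_band] / 360 * n_sectors)))
  dband <- band_index(depth[in_band], depth_bands, band_limits)
  ncell <- depth_bands * n_layers * n_sectors
  cell <- (dband - 1L) * n_layers * n_sectors + (layer - 1L) * n_sectors + sector
  count <- tabulate(cell, nbins = ncell)
  sums <- numeric(ncell)
  agg <- rowsum(vals, cell)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  mean_ecv <- ifelse(count > 0, sums / count, NA_real_)
  dimn <- c(depth_bands, n_layers, n_sectors)
  # cell index above is (dband, layer, sector) in row-major over
  # (layer, sector); rearrange into an R array [band, layer, sector]
  arr_mean <- array(NA_real_, dimn)
  arr_count <- array(0L, dimn)
  idx <- seq_len(ncell)
  b <- (idx - 1L) %/% (n_layers * n_sectors) + 1L
  rest <- (idx - 1L) %% (n_layers * n_sectors)
  l <- rest %/% n_sectors + 1L
  s <- rest %% n_sectors + 1L
  arr_mean[cbind(b, l, s)] <- mean_ecv
  arr_count[cbind(b, l, s)] <- count
  structure(list(mean_ecv = arr_mean, voxel_count = arr_count,
                 n_layers = as.integer(n_layers),
                 n_sectors = as.integer(n_sectors),
                 depth_bands = as.integer(depth_bands),
                 band_limits = band_limits,
                 voxel_mm3 = voxel_mm3(mask),
                 axis_length = geometry$length,
                 n_mask_voxels = length(sel),
                 n_discarded_axis = sum(on_axis),
                 n_out_of_band = sum(!in_band) - sum(on_axis & !in_band)),
            class = "compartment_grid")
}

#' @export
print.compartment_grid <- function(x, ...) {
  cat(sprintf("<compartment_grid> %d x %d x %d cells, %d voxels in band (%d near-axis discarded)\n",
              x$depth_bands, x$n_layers, x$n_sectors,
              sum(x$voxel_count), x$n_discarded_axis))
  invisible(x)
}

#' Map azimuth and ring to the AHA 16-segment number
#'
#' Basal (ring 1) and mid (ring 2) rings have six 60-degree segments, the
#' apical ring (ring 3) four 90-degree segments.  Segment 1 (basal
#' anterior) is centred on azimuth 0; numbering proceeds with increasing
#' azimuth (anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral).
#'
#' @param theta Azimuth in degrees.
#' @param ring Ring index 1 (basal), 2 (mid) or 3 (apical).
#' @return Integer segment numbers in 1..16.
#' @export
aha_segment <- function(theta, ring) {
  n <- max(length(theta), length(ring))
  theta <- rep_len(theta %% 360, n)
  ring <- rep_len(as.integer(ring), n)
  seg6 <- 1L + as.integer(floor(((theta + 30) %% 360) / 60))
  seg4 <- 1L + as.integer(floor(((theta + 45) %% 360) / 90))
  out <- integer(n)
  out[ring == 1L] <- seg6[ring == 1L]
  out[ring == 2L] <- 6L + seg6[ring == 2L]
  out[ring == 3L] <- 12L + seg4[ring == 3L]
  out
}

#' AHA 16-segment two-band aggregation of ECV
#'
#' The long axis is split into basal, mid and apical thirds; basal and mid
#' rings into six 60-degree sectors, the apical ring into four 90-degree
#' sectors, numbered per the standard AHA 16-segment scheme (segment 1 =
#' basal anterior, centred on the anterior reference).  Two transmural
#' bands are reported: subendocardium (fractional depth 0.10–0.50) and
#' subepicardium (0.50–0.90).
#'
#' @inheritParams build_compartments
#' @param band_limits Overall depth interval, split at its midpoint into
#'   the two bands (default 0.10–0.90).
#' @return A data frame with 32 rows: `segment` (1–16), `band`
#'   (`"subendo"`/`"subepi"`), `mean_ecv` (fraction, `NA` if empty),
#'   `voxel_count`.
#' @export
aha16_aggregate <- function(ecv, mask, geometry, band_limits = c(0.10, 0.90)) {
  grid <- build_compartments(ecv, mask, geometry, n_layers = 3L,
                             n_sectors = 360L, depth_bands = 2L,
                             band_limits = band_limits)
  # reuse the fine polar binning: 360 one-degree sectors x 3 rings, then
  # merge into AHA segments so ring/segment boundaries land exactly
  out <- expand.grid(band = c("subendo", "subepi"), segment = 1:16,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$segment, out$band), c("segment", "band")]
  rownames(out) <- NULL
  out$mean_ecv <- NA_real_
  out$voxel_count <- 0L
  theta_cent <- (seq_len(360L) - 0.5)
  for (ring in 1:3) {
    segs <- aha_segment(theta_cent, ring)
    for (b in 1:2) {
      cnt <- grid$voxel_count[b, ring, ]
      mu <- grid$mean_ecv[b, ring, ]
      sums <- ifelse(cnt > 0, mu * cnt, 0)
      for (s in unique(segs)) {
        pick <- segs == s
        n <- sum(cnt[pick])
        row <- which(out$segment == s & out$band == c("subendo", "subepi")[b])
        out$voxel_count[row] <- out$voxel_count[row] + n
        if (n > 0)
          out$mean_ecv[row] <- sum(sums[pick]) / n
      }
    }
  }
  attr(out, "band_limits") <- band_limits
  attr(out, "voxel_mm3") <- grid$voxel_mm3
  out
}

#' Export a compartment grid as CSV
#'
#' One row per compartment with columns `depth_layer` (1 = subendocardial),
#' `layer` (1 = base), `sector` (1 = anterior cut), `mean_ecv_percent`, and
#' `voxel_count`; header row, "." decimal separator.  Empty compartments
#' carry `NA`.  The default 3 x 34 x 72 grid yields 7344 data rows.
#'
#' @param grid A `compartment_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
compartments_to_csv <- function(grid, path) {
  idx <- expand.grid(sector = seq_len(grid$n_sectors),
                     layer = seq_len(grid$n_layers),
                     depth_layer = seq_len(grid$depth_bands),
                     KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(depth_layer = idx$depth_layer, layer = idx$layer,
                   sector = idx$sector)
  df$mean_ecv_percent <- 100 * grid$mean_ecv[cbind(df$depth_layer, df$layer, df$sector)]
  df$voxel_count <- grid$voxel_count[cbind(df$depth_layer, df$layer, df$sector)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
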