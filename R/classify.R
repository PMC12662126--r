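#' Configuration for pathologic-segment classification
#'
#' @param overlay_ecv Voxelwise ECV threshold (percent) for the overlay
#'   criterion (default 45).
#' @param overlay_min_cluster Minimum 6-connected voxel-cluster size
#'   within a segment-band for the overlay criterion (default 50, about
#'   10 mm^3 at 0.4 x 0.4 x 1.0 mm spacing); guards against single-voxel
#'   noise triggers.
#' @param polar_ecv Cell-mean ECV threshold (percent) for the polar
#'   criterion (default 45) applied to unfiltered two-band compartment
#'   means.
#' @param polar_fraction Minimal supra-threshold voxel fraction of the
#'   segment-band for the polar criterion (default 0.5).
#' @param atlas_ecv Filtered-cell ECV threshold (percent) for the atlas
#'   criterion (default 40; lower than the polar threshold because
#'   filtering smooths peaks).
#' @param atlas_fraction Minimal supra-threshold voxel fraction for the
#'   atlas criterion (default 0.25).
#' @param midwall How the three atlas depth layers map onto the two
#'   reported bands: `"split"` (default) weights the midwall layer half
#'   into each band; `"both"` counts it fully in both.
#' @param criteria Character subset of `c("overlay", "polar", "atlas")`
#'   to evaluate.
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(overlay_ecv = 45, overlay_min_cluster = 50L,
                            polar_ecv = 45, polar_fraction = 0.5,
                            atlas_ecv = 40, atlas_fraction = 0.25,
                            midwall = c("split", "both"),
                            criteria = c("overlay", "polar", "atlas")) {
  midwall <- match.arg(midwall)
  criteria <- match.arg(criteria, several.ok = TRUE)
  structure(list(overlay_ecv = overlay_ecv,
                 overlay_min_cluster = as.integer(overlay_min_cluster),
                 polar_ecv = polar_ecv, polar_fraction = polar_fraction,
                 atlas_ecv = atlas_ecv, atlas_fraction = atlas_fraction,
                 midwall = midwall, criteria = criteria),
            class = "classify_config")
}

# per-voxel segment/band labels for all myocardial voxels within the
# band limits; returns NULL labels for out-of-band voxels
voxel_segment_bands <- function(mask, geometry, band_limits = c(0.10, 0.90)) {
  sel <- which(mask$values != 0)
  ctr <- voxel_centers(mask)
  pts <- cbind(ctr$x[sel], ctr$y[sel], ctr$z[sel])
  co <- lv_coords(geometry, pts)
  depth <- if (geometry$type == "mask") wall_depth_mask(geometry, pts)
           else wall_depth(geometry, pts, strict = FALSE)
  r_min <- min(mask$spacing[1:2])
  keep <- co$r >= r_min & is.finite(depth) &
    depth >= band_limits[1] & depth <= band_limits[2] &
    co$z >= 0 & co$z <= geometry$length
  ring <- pmin(3L, pmax(1L, 1L + as.integer(floor(co$z / geometry$length * 3))))
  segment <- aha_segment(co$theta, ring)
  band <- band_index(depth, 2L, band_limits)
  n_layers34 <- 34L; n_sectors72 <- 72L
  layer34 <- pmin(n_layers34, pmax(1L, 1L + as.integer(floor(co$z / geometry$length * n_layers34))))
  sector72 <- pmin(n_sectors72, 1L + as.integer(floor(co$theta / 360 * n_sectors72)))
  band3 <- band_index(depth, 3L, band_limits)
  list(sel = sel, keep = keep, segment = segment, band = band,
       layer34 = layer34, sector72 = sector72, band3 = band3)
}

#' Classify pathologic myocardial segments
#'
#' Applies the automated pathologic-segment criteria to each of the 32
#' segment-bands (AHA segments 1–16, subendocardium and subepicardium):
#'
#' * overlay — the segment-band contains a 6-connected cluster of at
#'   least `overlay_min_cluster` voxels with voxelwise ECV above
#'   `overlay_ecv` percent (clipped ECV, as rendered in overlay images);
#' * polar — more than `polar_fraction` of the segment-band's voxels lie
#'   in unfiltered two-band compartment cells (34 x 72, matched band)
#'   with mean ECV above `polar_ecv` percent;
#' * atlas — more than `atlas_fraction` of the segment-band's voxels lie
#'   in median-filtered atlas cells with ECV above `atlas_ecv` percent,
#'   with the three atlas depth layers apportioned onto the two bands per
#'   `config$midwall`.
#'
#' A segment-band is pathologic if any enabled criterion fires (logical
#' OR).  Visual hyperenhancement reading of the late-enhancement images
#' is human interpretation; supply it, if available, as `external_calls`
#' (logical vector of 32, ordered segment 1 subendo, segment 1 subepi,
#' ...) and it is merged by OR.
#'
#' @param ecv An [ecv_volume()].
#' @param mask Myocardium mask ([voxel_volume()]).
#' @param geometry An [lv_geometry()].
#' @param grid Optional precomputed 3-band `compartment_grid` (built if
#'   missing).
#' @param atlas Optional precomputed `atlas_map` (built if missing).
#' @param external_calls Optional logical vector of 32 externally read
#'   calls.
#' @param config A [classify_config()].
#' @param band_limits Fractional-depth interval analysed.
#' @return A data frame of 32 rows: `segment`, `band`, `pathologic`,
#'   per-criterion logicals (`overlay`, `polar`, `atlas`, `external`),
#'   supporting fractions, and `criteria` (comma-joined triggered
#'   criteria).
#' @export
classify_segments <- function(ecv, mask, geometry, grid = NULL, atlas = NULL,
                              external_calls = NULL,
                              config = classify_config(),
                              band_limits = c(0.10, 0.90)) {
  stopifnot(inherits(ecv, "ecv_volume"))
  stopifnot_same_grid(ecv$volume, mask, "ECV and mask")
  if (is.null(grid))
    grid <- build_compartments(ecv, mask, geometry, band_limits = band_limits)
  if (is.null(atlas)) atlas <- build_atlas(grid)
  if (grid$depth_bands != 3L)
    stop("classification expects a 3-depth-band compartment grid")
  polar_grid <- build_compartments(ecv, mask, geometry, depth_bands = 2L,
                                   band_limits = band_limits)
  lab <- voxel_segment_bands(mask, geometry, band_limits)
  keep <- lab$keep
  segband <- (lab$segment - 1L) * 2L + lab$band       # 1..32
  out <- data.frame(segment = rep(1:16, each = 2),
                    band = rep(c("subendo", "subepi"), 16),
                    stringsAsFactors = FALSE)
  total <- tabulate(segband[keep], nbins = 32L)

  # --- overlay criterion: voxel clusters above overlay_ecv ---------------
  clip <- pmin(pmax(ecv$volume$values, 0), 1)
  supra <- array(FALSE, dim = dim(clip))
  supra[lab$sel] <- TRUE                    # restrict to myocardium
  supra <- supra & clip > config$overlay_ecv / 100
  labarr <- .label_components_cpp(as.logical(supra), dim(supra))
  comp <- labarr[lab$sel][keep]
  sb <- segband[keep]
  overlay_frac <- numeric(32)
  overlay_hit <- rep(FALSE, 32)
  pos <- comp > 0
  if (any(pos)) {
    tab <- table(sb[pos], comp[pos])
    rows <- as.integer(rownames(tab))
    overlay_hit[rows] <- apply(tab, 1, max) >= config$overlay_min_cluster
    overlay_frac[rows] <- rowSums(tab) / total[rows]
  }

  # --- polar criterion: unfiltered 2-band cell means ---------------------
  cellmean2 <- polar_grid$mean_ecv[cbind(lab$band, lab$layer34, lab$sector72)]
  polar_sup <- keep & !is.na(cellmean2) & cellmean2 * 100 > config$polar_ecv
  polar_frac <- tabulate(segband[polar_sup], nbins = 32L) / pmax(total, 1L)
  polar_hit <- polar_frac > config$polar_fraction

  # --- atlas criterion: filtered 3-layer cells, midwall apportioned ------
  sup3 <- vapply(1:3, function(b) {
    f <- atlas$layers[[b]]$filtered
    m <- !is.na(f) & f > config$atlas_ecv
    m[cbind(lab$layer34, lab$sector72)]
  }, logical(length(lab$layer34)))
  vox_sup3 <- sup3[cbind(seq_along(lab$band3), lab$band3)]
  atlas_num <- numeric(32); atlas_den <- numeric(32)
  contrib <- function(target_band) {
    # voxels counted toward `target_band`: their own band for layers 1/3,
    # midwall voxels toward both bands (weighted)
    if (config$midwall == "split") {
      own <- (lab$band3 == 1L & target_band == 1L) |
             (lab$band3 == 3L & target_band == 2L)
      mid <- lab$band3 == 2L
      wts <- ifelse(own, 1, ifelse(mid, 0.5, 0))
    } else {
      own <- (lab$band3 == 1L & target_band == 1L) |
             (lab$band3 == 3L & target_band == 2L) | lab$band3 == 2L
      wts <- ifelse(own, 1, 0)
    }
    wts
  }
  segonly <- (lab$segment - 1L) * 2L
  for (tb in 1:2) {
    wts <- contrib(tb)
    use <- keep & wts > 0
    idx <- segonly[use] + tb
    atlas_den_tb <- rowsum(wts[use], idx)
    atlas_den[as.integer(rownames(atlas_den_tb))] <-
      atlas_den[as.integer(rownames(atlas_den_tb))] + atlas_den_tb[, 1]
    usev <- use & vox_sup3
    if (any(usev)) {
      idn <- segonly[usev] + tb
      atlas_num_tb <- rowsum(wts[usev], idn)
      atlas_num[as.integer(rownames(atlas_num_tb))] <-
        atlas_num[as.integer(rownames(atlas_num_tb))] + atlas_num_tb[, 1]
    }
  }
  atlas_frac <- ifelse(atlas_den > 0, atlas_num / atlas_den, 0)
  atlas_hit <- atlas_frac > config$atlas_fraction

  if (!"overlay" %in% config$criteria) overlay_hit[] <- FALSE
  if (!"polar" %in% config$criteria) polar_hit[] <- FALSE
  if (!"atlas" %in% config$criteria) atlas_hit[] <- FALSE
  ext <- if (is.null(external_calls)) rep(FALSE, 32) else {
    stopifnot(length(external_calls) == 32L)
    as.logical(external_calls)
  }

  out$overlay <- overlay_hit
  out$polar <- polar_hit
  out$atlas <- atlas_hit
  out$external <- ext
  out$pathologic <- overlay_hit | polar_hit | atlas_hit | ext
  out$overlay_fraction <- overlay_frac
  out$polar_fraction <- polar_frac
  out$atlas_fraction <- atlas_frac
  out$voxel_count <- total
  out$criteria <- vapply(seq_len(32), function(i) {
    paste(c("overlay", "polar", "atlas", "external")[
      c(overlay_hit[i], polar_hit[i], atlas_hit[i], ext[i])], collapse = ",")
  }, character(1))
  class(out) <- c("segment_calls", "data.frame")
  out
}

#' Collapse segment-band calls to per-segment calls
#'
#' A segment is affected if either its subendocardium or its
#' subepicardium is pathologic.
#'
#' @param calls A `segment_calls` data frame from [classify_segments()].
#' @return Named logical vector of length 16.
#' @export
segments_affected <- function(calls) {
  stopifnot(all(c("segment", "pathologic") %in% names(calls)))
  aff <- tapply(calls$pathologic, calls$segment, any)
  out <- as.logical(aff[as.character(1:16)])
  names(out) <- 1:16
  out
}

#' Write segment calls as CSV
#' @param calls A `segment_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
calls_to_csv <- function(calls, path) {
  utils::write.csv(as.data.frame(calls), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference segment calls from CSV
#'
#' Expected columns: `segment` (1–16), `band` (`"subendo"`, `"subepi"` or
#' `"wall"` for calls that do not distinguish bands), `positive` (0/1).
#'
#' @param path CSV path.
#' @return A data frame with columns `segment`, `band`, `positive`.
#' @export
read_reference_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "band", "positive")
  if (!all(need %in% names(df)))
    stop(sprintf("reference calls CSV must have columns %s",
                 paste(need, collapse = ", ")))
  df$positive <- as.integer(df$positive)
  df
}
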