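#' Median-filter a layer-by-sector matrix
#'
#' Each cell is replaced by the median of its `kernel` x `kernel`
#' neighbourhood.  The angular (sector) dimension wraps circularly — the
#' anterior cut of the myocardial ring is arbitrary, so filtering must
#' commute with rotating the cut — and the longitudinal (layer) edges are
#' replicated.  `NaN` cells (empty compartments) are excluded from each
#' window's median; an all-`NaN` window stays `NaN`.
#'
#' @param matrix A numeric matrix, rows = layers (base to apex), columns =
#'   angular sectors.
#' @param kernel Odd positive integer window size (default 5).
#' @return The filtered matrix.
#' @export
median_filter_matrix <- function(matrix, kernel = 5L) {
  if (!is.matrix(matrix)) stop("`matrix` must be a matrix")
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be an odd positive integer")
  if (kernel == 1L) return(matrix)
  storage.mode(matrix) <- "double"
  .median_filter_cpp(matrix, kernel)
}

#' Build an atlas map from a compartment grid
#'
#' For each transmural depth layer, the 34 x 72 mean-ECV matrix (in
#' percent) is median-filtered to suppress non-connected speckle noise,
#' then thresholded at 45%, 40% and 35% ECV — markers of a descending
#' probability for the presence of a focal lesion (strict `>`,
#' full-precision values).  The volume percentage of each layer above each
#' threshold is voxel-count weighted:
#' `100 * sum(count over cells with filtered ECV > t) / sum(count over
#' non-empty cells of the layer)`.
#'
#' @param grid A `compartment_grid` from [build_compartments()].
#' @param kernel Median-filter window (default 5).
#' @param thresholds ECV thresholds in percent (default `c(35, 40, 45)`).
#' @return An object of class `atlas_map`: per depth layer a
#'   `filtered` percent matrix, logical `masks` per threshold, and
#'   `volume_percent` per threshold; plus provenance (kernel, boundary
#'   policy, thresholds).
#' @export
build_atlas <- function(grid, kernel = 5L, thresholds = c(35, 40, 45)) {
  stopifnot(inherits(grid, "compartment_grid"))
  thresholds <- sort(as.numeric(thresholds))
  layers <- vector("list", grid$depth_bands)
  for (b in seq_len(grid$depth_bands)) {
    cnt <- matrix(grid$voxel_count[b, , ], grid$n_layers, grid$n_sectors)
    if (all(cnt == 0))
      stop(sprintf("depth layer %d has no voxels; cannot build atlas map", b))
    m <- matrix(100 * grid$mean_ecv[b, , ], grid$n_layers, grid$n_sectors)
    filt <- median_filter_matrix(m, kernel)
    masks <- lapply(thresholds, function(t) !is.na(filt) & filt > t)
    names(masks) <- as.character(thresholds)
    total <- sum(cnt[cnt > 0])
    vp <- vapply(masks, function(mk) 100 * sum(cnt[mk]) / total, numeric(1))
    layers[[b]] <- list(filtered = filt, masks = masks, volume_percent = vp)
  }
  structure(list(layers = layers, kernel = as.integer(kernel),
                 thresholds = thresholds,
                 boundary = "sectors wrap circularly; layer edges replicate",
                 n_layers = grid$n_layers, n_sectors = grid$n_sectors,
                 voxel_mm3 = grid$voxel_mm3),
            class = "atlas_map")
}

#' @export
print.atlas_map <- function(x, ...) {
  cat(sprintf("<atlas_map> %d depth layers, %d x %d cells, %dx%d median filter\n",
              length(x$layers), x$n_layers, x$n_sectors, x$kernel, x$kernel))
  for (b in seq_along(x$layers)) {
    vp <- x$layers[[b]]$volume_percent
    cat(sprintf("  layer %d: %% volume above %s = %s\n", b,
                paste(names(vp), collapse = "/"),
                paste(sprintf("%.1f", vp), collapse = "/")))
  }
  invisible(x)
}

#' Absolute scar volume above an ECV threshold
#'
#' Sum over supra-threshold atlas cells of their voxel count times the
#' voxel volume.
#'
#' @param atlas An `atlas_map`.
#' @param grid The `compartment_grid` the atlas was built from.
#' @param threshold One of the atlas thresholds (percent ECV).
#' @return Scar volume in mm^3.
#' @export
scar_volume <- function(atlas, grid, threshold) {
  key <- as.character(threshold)
  if (!key %in% names(atlas$layers[[1]]$masks))
    stop(sprintf("threshold %s not among atlas thresholds (%s)", key,
                 paste(atlas$thresholds, collapse = ", ")))
  total <- 0
  for (b in seq_along(atlas$layers)) {
    cnt <- matrix(grid$voxel_count[b, , ], grid$n_layers, grid$n_sectors)
    total <- total + sum(cnt[atlas$layers[[b]]$masks[[key]]])
  }
  total * grid$voxel_mm3
}

ecv_color_ramp <- function() {
  grDevices::colorRampPalette(c("#2c2c6e", "#2166ac", "#35978f", "#5aae61",
                                "#d9ef8b", "#fdae61", "#d73027", "#7f0000"))
}

atlas_level_colors <- function() {
  # neutral base plus three alert levels of descending lesion probability
  c(base = "#f0f0f0", weak = "#fee391", mid = "#fe9929", strong = "#cc4c02")
}

# R's pdf() embeds creation/modification timestamps; zero their digits so
# renders are byte-stable for fixed input (same-length replacement keeps
# the xref offsets valid).
sanitize_pdf_timestamps <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  zero <- charToRaw("0")
  digits <- as.raw(48:57)
  for (pat in c("/CreationDate (D:", "/ModDate (D:")) {
    for (h in grepRaw(pat, raw, fixed = TRUE, all = TRUE)) {
      i <- h + nchar(pat)
      while (i <= length(raw) && raw[i] %in% digits) {
        raw[i] <- zero
        i <- i + 1L
      }
    }
  }
  writeBin(raw, path)
  invisible(path)
}

#' Render a 16-segment polar map
#'
#' Standard AHA bullseye (base at the rim, apex at the centre; anterior
#' up), one wheel per transmural band (subendocardium, subepicardium),
#' segments coloured on a continuous scale with fixed range 0–60% ECV.
#' Output PDFs are byte-stable for fixed input (timestamps are
#' suppressed).
#'
#' @param polar A data frame as returned by [aha16_aggregate()].
#' @param out Output PDF path.
#' @param title Plot title.
#' @return `out`, invisibly.
#' @export
render_polar <- function(polar, out, title = "ECV polar map") {
  ramp <- ecv_color_ramp()(256)
  col_of <- function(ecv_pct) {
    i <- 1 + round(pmin(pmax(ecv_pct, 0), 60) / 60 * 255)
    ifelse(is.na(ecv_pct), "#bbbbbb", ramp[i])
  }
  wedge <- function(r0, r1, a0, a1, col) {
    # angles in degrees, 90 = anterior (up); drawn clockwise on screen
    aa <- seq(a0, a1, length.out = 32) * pi / 180
    px <- c(r0 * cos(aa), rev(r1 * cos(aa)))
    py <- c(r0 * sin(aa), rev(r1 * sin(aa)))
    graphics::polygon(px, py, col = col, border = "white")
  }
  grDevices::pdf(out, width = 9, height = 5.2, compress = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
  for (band in c("subendo", "subepi")) {
    graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("%s (%s)", title, band))
    sub <- polar[polar$band == band, ]
    radii <- c(0.25, 0.62, 0.85, 1.08)   # apex..base ring boundaries
    for (seg in 1:16) {
      ring <- if (seg <= 6) 1L else if (seg <= 12) 2L else 3L
      within <- if (ring == 3L) seg - 13L else (seg - 1L) %% 6L
      span <- if (ring == 3L) 90 else 60
      # screen angle: anterior (azimuth 0) up, azimuth increases clockwise
      a0 <- 90 - (within * span - span / 2)
      a1 <- a0 - span
      v <- 100 * sub$mean_ecv[sub$segment == seg]
      wedge(radii[4 - ring], radii[5 - ring], a1, a0, col_of(v))
      am <- (a0 + a1) / 2 * pi / 180
      rm <- (radii[4 - ring] + radii[5 - ring]) / 2
      graphics::text(rm * cos(am), rm * sin(am), seg, cex = 0.6)
    }
    leg_y <- seq(-1.1, -1.2, length.out = 2)
    graphics::rect(seq(-1, 0.9, length.out = 64), leg_y[1],
                   seq(-1, 0.9, length.out = 64) + 0.03, leg_y[2],
                   col = ecv_color_ramp()(64), border = NA)
    graphics::text(c(-1, 0.95), leg_y[1] + 0.05, c("0%", "60%"), cex = 0.6)
  }
  grDevices::dev.off()
  on.exit()
  sanitize_pdf_timestamps(out)
  invisible(out)
}

#' Render an atlas map
#'
#' Three stacked 34 x 72 panels (subendocardium on top panel order 1..3;
#' base at the top of each panel, anterior cut at the left edge), cells
#' coloured by the three-level threshold code (>45% strongest, 40–45%
#' mid, 35–40% weak, below 35% uncoloured), each panel annotated with its
#' volume percentages above 45/40/35% ECV.  Output PDFs are byte-stable
#' for fixed input (timestamps are suppressed).
#'
#' @param atlas An `atlas_map`.
#' @param out Output PDF path.
#' @param title Plot title.
#' @return `out`, invisibly.
#' @export
render_atlas <- function(atlas, out, title = "ECV atlas map") {
  cols <- atlas_level_colors()
  lvl_names <- c("subendocardium", "midwall", "subepicardium")
  th <- sort(atlas$thresholds)          # 35, 40, 45
  grDevices::pdf(out, width = 8, height = 9, compress = FALSE)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(length(atlas$layers), 1), mar = c(2.5, 3, 3, 1))
  for (b in seq_along(atlas$layers)) {
    lay <- atlas$layers[[b]]
    code <- matrix(0L, atlas$n_layers, atlas$n_sectors)
    for (k in seq_along(th)) code[lay$masks[[as.character(th[k])]]] <- k
    # image(): x = sectors, y = layers with base (layer 1) at the top
    z <- t(code[atlas$n_layers:1, , drop = FALSE])
    graphics::image(x = seq_len(atlas$n_sectors), y = seq_len(atlas$n_layers),
                    z = z, zlim = c(0, 3), col = unname(cols),
                    axes = FALSE, xlab = "", ylab = "",
                    main = sprintf("%s - %s", title,
                                   if (b <= 3) lvl_names[b] else sprintf("layer %d", b)))
    graphics::axis(1, at = c(1, 18, 36, 54, 72), cex.axis = 0.7)
    graphics::axis(2, at = c(1, 34), labels = c("apex", "base"), cex.axis = 0.7)
    vp <- lay$volume_percent
    graphics::mtext(sprintf(">45%%: %.1f  >40%%: %.1f  >35%%: %.1f",
                            vp[["45"]], vp[["40"]], vp[["35"]]),
                    side = 1, line = 1.3, cex = 0.7)
  }
  grDevices::dev.off()
  on.exit()
  sanitize_pdf_timestamps(out)
  invisible(out)
}
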