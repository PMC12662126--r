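test_that("median filter basics: constants, speckle, kernels", {
  m <- matrix(27, 34, 72)
  expect_equal(median_filter_matrix(m, 5), m)
  sp <- m; sp[17, 36] <- 60
  expect_equal(median_filter_matrix(sp, 5), m)      # isolated speckle removed
  expect_equal(median_filter_matrix(sp, 1), sp)     # identity kernel
  expect_error(median_filter_matrix(m, 4), "odd")
  expect_error(median_filter_matrix(m, 0), "odd")
})

test_that("median filter is idempotent on edge-free piecewise-constant regions", {
  ring <- matrix(27, 34, 72); ring[10:20, ] <- 55   # full circumferential band
  expect_equal(median_filter_matrix(ring, 5), ring)
  wedge <- matrix(27, 34, 72); wedge[, 30:45] <- 55 # full-height wedge
  expect_equal(median_filter_matrix(wedge, 5), wedge)
  # core cells of a 5x5-or-larger block survive unchanged (1 cm surface)
  m <- matrix(27, 34, 72)
  m[10:20, 30:45] <- 55
  f1 <- median_filter_matrix(m, 5)
  expect_equal(f1[12:18, 32:43], m[12:18, 32:43])
})

test_that("filtering commutes with rotating the anterior cut", {
  set.seed(7)
  m <- matrix(rnorm(34 * 72, 27, 5), 34, 72)
  rot <- function(x, k) x[, c((k + 1):ncol(x), 1:k)]
  for (k in c(1, 13, 40)) {
    expect_equal(median_filter_matrix(rot(m, k), 5),
                 rot(median_filter_matrix(m, 5), k))
  }
})

test_that("NaN cells are excluded from windows and all-NaN windows stay NaN", {
  m <- matrix(27, 34, 72)
  m[34, ] <- NaN                                    # empty apex row
  f <- median_filter_matrix(m, 5)
  expect_equal(f[1:33, ], m[1:33, ])                # not poisoned
  expect_equal(f[34, ], rep(27, 72))                # median of remaining cells
  m2 <- matrix(NaN, 10, 10)
  expect_true(all(is.na(median_filter_matrix(m2, 3))))
})

test_that("atlas thresholds are strict and volume percentages nest", {
  ph <- generate_phantom(coarse_spec(background_ecv = 0.41))
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  for (lay in atlas$layers) {
    expect_equal(unname(lay$volume_percent[c("35", "40", "45")]),
                 c(100, 100, 0))                    # 41 > 40 but not > 45
  }
})

test_that("threshold masks nest and percentages are monotone under noise", {
  spec <- coarse_spec(noise_sigma = 1.2, seed = 9L)
  ph <- generate_phantom(spec)
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  for (lay in atlas$layers) {
    expect_true(all(lay$masks[["45"]] <= lay$masks[["40"]]))
    expect_true(all(lay$masks[["40"]] <= lay$masks[["35"]]))
    vp <- lay$volume_percent
    expect_true(vp[["45"]] <= vp[["40"]] && vp[["40"]] <= vp[["35"]])
    expect_true(all(vp >= 0 & vp <= 100))
  }
})

test_that("filtering suppresses lesion-free noise below the 45% threshold", {
  spec <- coarse_spec()
  sigma <- sigma_for_cell_noise(spec, cell_pct = 4)  # ~4% ECV per raw cell
  ph <- generate_phantom(coarse_spec(noise_sigma = sigma, seed = 21L))
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  for (lay in atlas$layers) expect_equal(lay$volume_percent[["45"]], 0)
})

test_that("a subendocardial lesion marks only depth layer 1 above 45%", {
  les <- lesion_spec(layer = 12, sector = 30, angular_extent = 25,
                     longitudinal_extent = 12,
                     transmural_range = c(0.10, 0.35), lesion_ecv = 0.55)
  ph <- generate_phantom(phantom_spec(voxel_spacing = c(0.8, 0.8, 1),
                                      lesions = list(les)))
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  expect_gt(sum(atlas$layers[[1]]$masks[["45"]]), 0)
  expect_equal(sum(atlas$layers[[2]]$masks[["45"]]), 0)
  expect_equal(sum(atlas$layers[[3]]$masks[["45"]]), 0)
  hot <- which(atlas$layers[[1]]$masks[["45"]], arr.ind = TRUE)
  expect_true(all(hot[, 1] >= 8 & hot[, 1] <= 16))   # 12 mm around layer 12
  expect_true(all(hot[, 2] >= 26 & hot[, 2] <= 34))  # 25 deg around sector 30
})

test_that("scar volume approximates the in-band lesion volume", {
  mk <- function(ext) {
    les <- lesion_spec(center_z = 25, center_theta = 180, angular_extent = ext,
                       longitudinal_extent = 30, transmural_range = c(0, 1),
                       lesion_ecv = 0.55)
    generate_phantom(phantom_spec(voxel_spacing = c(0.8, 0.8, 1),
                                  lesions = list(les)))
  }
  in_band_volume <- function(ph) {
    mask <- ph$truth$lesion_mask
    sel <- which(mask$values != 0)
    d <- dim(mask$values); ijk <- arrayInd(sel, d)
    pts <- cbind(mask$origin[1] + (ijk[, 1] - 1) * mask$spacing[1],
                 mask$origin[2] + (ijk[, 2] - 1) * mask$spacing[2],
                 mask$origin[3] + (ijk[, 3] - 1) * mask$spacing[3])
    depth <- wall_depth(ph$truth$geometry, pts, strict = FALSE)
    sum(depth >= 0.1 & depth <= 0.9) * prod(mask$spacing)
  }
  ph <- mk(60)
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  ph0 <- generate_phantom(coarse_spec())
  g0 <- build_compartments(phantom_ecv(ph0), ph0$truth$myocardium_mask,
                           ph0$truth$geometry)
  expect_equal(scar_volume(build_atlas(g0), g0, 45), 0)
  v40 <- scar_volume(atlas, g, 45)
  expect_lt(abs(v40 / in_band_volume(ph) - 1), 0.15)
  ph2 <- mk(120)
  ecv2 <- phantom_ecv(ph2)
  g2 <- build_compartments(ecv2, ph2$truth$myocardium_mask, ph2$truth$geometry)
  v80 <- scar_volume(build_atlas(g2), g2, 45)
  expect_gt(v80 / v40, 1.7)
  expect_lt(v80 / v40, 2.3)
  expect_error(scar_volume(atlas, g, 50), "not among")
})

test_that("renders are written and byte-stable for fixed input", {
  les <- lesion_spec(center_z = 20, center_theta = 0, angular_extent = 40,
                     longitudinal_extent = 20, transmural_range = c(0, 1),
                     lesion_ecv = 0.55)
  ph <- generate_phantom(coarse_spec(lesions = list(les)))
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  polar <- aha16_aggregate(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  d <- tempdir()
  a1 <- file.path(d, "a1.pdf"); a2 <- file.path(d, "a2.pdf")
  p1 <- file.path(d, "p1.pdf"); p2 <- file.path(d, "p2.pdf")
  render_atlas(atlas, a1); render_atlas(atlas, a2)
  render_polar(polar, p1); render_polar(polar, p2)
  for (f in c(a1, a2, p1, p2)) expect_gt(file.size(f), 1000)
  expect_identical(readBin(a1, "raw", file.size(a1)),
                   readBin(a2, "raw", file.size(a2)))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # annotations in the PDF text stream match the computed percentages
  raw1 <- readBin(a1, "raw", file.size(a1))
  expect_gt(length(grepRaw(sprintf("%.1f", atlas$layers[[1]]$volume_percent[["45"]]),
                           raw1, fixed = TRUE, all = TRUE)), 0)
})

test_that("a uniform background atlas renders with zero percentages", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  atlas <- build_atlas(g)
  f <- file.path(tempdir(), "uniform.pdf")
  render_atlas(atlas, f)
  rawf <- readBin(f, "raw", file.size(f))
  expect_gt(length(grepRaw(">45%: 0.0", rawf, fixed = TRUE, all = TRUE)), 0)
  expect_true(all(vapply(atlas$layers,
                         function(l) all(l$volume_percent == 0), logical(1))))
})
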