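# independent brute-force compartment assignment used as the conservation
# oracle: plain trigonometry on every mask voxel, no shared code path
brute_force_counts <- function(ph, n_layers = 34, n_sectors = 72,
                               bands = 3, lim = c(0.1, 0.9)) {
  mask <- ph$truth$myocardium_mask
  sel <- which(mask$values != 0)
  d <- dim(mask$values)
  ijk <- arrayInd(sel, d)
  x <- mask$origin[1] + (ijk[, 1] - 1) * mask$spacing[1]
  y <- mask$origin[2] + (ijk[, 2] - 1) * mask$spacing[2]
  z <- mask$origin[3] + (ijk[, 3] - 1) * mask$spacing[3]
  r <- sqrt(x^2 + y^2)
  L <- ph$spec$lv_length
  Ro <- ph$spec$outer_diameter / 2
  Ri <- Ro - ph$spec$wall_thickness
  Lc <- L - Ro
  re <- ifelse(z <= Lc, Ri, sqrt(pmax(Ri^2 - (z - Lc)^2, 0)))
  rp <- ifelse(z <= Lc, Ro, sqrt(pmax(Ro^2 - (z - Lc)^2, 0)))
  depth <- (r - re) / (rp - re)
  keep <- r >= min(mask$spacing[1:2]) & depth >= lim[1] & depth <= lim[2]
  sum(keep)
}

test_that("wall depth is linear in radius between the surfaces", {
  geo <- lv_geometry(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), length = 45,
                     r_endo = function(z) rep(15, length(z)),
                     r_epi = function(z) rep(25, length(z)))
  pts <- rbind(c(15, 0, 10), c(20, 0, 10), c(25, 0, 10),
               c(0, 17.5, 30))
  expect_equal(wall_depth(geo, pts), c(0, 0.5, 1, 0.25))
  expect_error(wall_depth(geo, c(5, 0, 10)), "outside")
  expect_error(wall_depth(geo, c(20, 0, 50)), "outside")
  expect_error(lv_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), 45,
                           identity, identity), "degenerate")
  expect_error(lv_geometry(c(0, 0, 0), c(0, 0, 1), c(0, 0.5, 0.5), 45,
                           identity, identity), "perpendicular")
})

test_that("mask-derived depth agrees with analytic depth within one voxel", {
  ph <- generate_phantom(phantom_spec(voxel_spacing = c(0.8, 0.8, 1)))
  mask <- ph$truth$myocardium_mask
  geo_m <- geometry_from_mask(mask)
  sel <- which(mask$values != 0)
  set.seed(2)
  sel <- sample(sel, 3000)
  d <- dim(mask$values)
  ijk <- arrayInd(sel, d)
  pts <- cbind(mask$origin[1] + (ijk[, 1] - 1) * mask$spacing[1],
               mask$origin[2] + (ijk[, 2] - 1) * mask$spacing[2],
               mask$origin[3] + (ijk[, 3] - 1) * mask$spacing[3])
  # interior (cylindrical) region: surface tables near the apex cap are too
  # coarse for a voxel-level comparison
  cyl <- pts[, 3] < ph$spec$lv_length - ph$spec$outer_diameter / 2
  da <- wall_depth(ph$truth$geometry, pts[cyl, ], strict = FALSE)
  dm <- ecvatlas:::wall_depth_mask(geo_m, pts[cyl, ])
  # one voxel spacing expressed as a depth fraction of the 10 mm wall
  tol <- max(mask$spacing) / ph$spec$wall_thickness
  expect_lt(stats::quantile(abs(da - dm), 0.98), tol)
})

test_that("compartment assignment is a partition that conserves voxels", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  expect_equal(length(g$mean_ecv), 3 * 34 * 72)     # 7344 cells
  expect_equal(sum(g$voxel_count), brute_force_counts(ph))
  expect_true(all(is.finite(g$mean_ecv[g$voxel_count > 0])))
  expect_true(all(is.na(g$mean_ecv[g$voxel_count == 0])))
})

test_that("a uniform field yields exactly the background in every cell", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  expect_equal(unique(round(g$mean_ecv[g$voxel_count > 0], 12)), 0.27)
  expect_error(build_compartments(ecv,
    voxel_volume(array(0, dim(ph$iodine$values)), ph$iodine$spacing,
                 ph$iodine$origin),
    ph$truth$geometry), "empty")
})

test_that("a subendocardial lesion elevates only the predicted cells", {
  les <- lesion_spec(layer = 10, sector = 20, angular_extent = 20,
                     longitudinal_extent = 10,
                     transmural_range = c(0.10, 0.35), lesion_ecv = 0.55)
  ph <- generate_phantom(phantom_spec(voxel_spacing = c(0.8, 0.8, 1),
                                      lesions = list(les)))
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  hot <- which(g$mean_ecv > 0.28, arr.ind = TRUE)
  expect_gt(nrow(hot), 0)
  expect_true(all(hot[, 1] == 1))                   # subendocardial band only
  # lesion centred at layer 10 / sector 20: 10 mm ~ +-2.5 layers,
  # 20 deg ~ +-2 sectors
  expect_true(all(hot[, 2] >= 7 & hot[, 2] <= 13))
  expect_true(all(hot[, 3] >= 17 & hot[, 3] <= 23))
})

test_that("rotating a lesion by multiples of 5 degrees shifts sectors exactly", {
  hot_sectors <- function(extra_deg) {
    # lesion edges placed mid-sector so cell membership is unambiguous
    les <- lesion_spec(center_z = 20, center_theta = 92.5 + extra_deg,
                       angular_extent = 20, longitudinal_extent = 10,
                       transmural_range = c(0, 1), lesion_ecv = 0.55)
    ph <- generate_phantom(coarse_spec(lesions = list(les)))
    ecv <- phantom_ecv(ph)
    g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
    sort(unique(which(g$mean_ecv > 0.28, arr.ind = TRUE)[, 3]))
  }
  base <- hot_sectors(0)
  for (k in c(1, 3, 7)) {
    shifted <- hot_sectors(k * 5)
    expect_equal(shifted, sort((base + k - 1) %% 72 + 1))
  }
})

test_that("AHA-16 aggregation localises a basal anterior lesion", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  flat <- aha16_aggregate(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  expect_equal(nrow(flat), 32)
  expect_equal(unique(round(flat$mean_ecv, 12)), 0.27)

  les <- lesion_spec(center_z = 11, center_theta = 0, angular_extent = 40,
                     longitudinal_extent = 20, transmural_range = c(0, 1),
                     lesion_ecv = 0.55)
  ph2 <- generate_phantom(coarse_spec(lesions = list(les)))
  ecv2 <- phantom_ecv(ph2)
  a <- aha16_aggregate(ecv2, ph2$truth$myocardium_mask, ph2$truth$geometry)
  seg1 <- a[a$segment == 1, ]
  expect_true(all(seg1$mean_ecv > 0.35))            # elevated in both bands
  far <- a[a$segment %in% c(3, 4, 5, 9, 10, 11, 13:16), ]
  expect_equal(unique(round(far$mean_ecv, 12)), 0.27)
})

test_that("AHA-16 band voxel totals match direct depth-band counts", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  a <- aha16_aggregate(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  g2 <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry,
                           depth_bands = 2L)
  for (b in 1:2) {
    band <- c("subendo", "subepi")[b]
    expect_equal(sum(a$voxel_count[a$band == band]), sum(g2$voxel_count[b, , ]))
  }
})

test_that("AHA-16 means refine from compatible compartment grids", {
  les <- lesion_spec(center_z = 30, center_theta = 120, angular_extent = 50,
                     longitudinal_extent = 25, transmural_range = c(0, 1),
                     lesion_ecv = 0.50)
  ph <- generate_phantom(coarse_spec(lesions = list(les)))
  ecv <- phantom_ecv(ph)
  a <- aha16_aggregate(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  # 33 layers (11 per ring) and 72 sectors subdivide the AHA partition
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry,
                          n_layers = 33L, depth_bands = 2L)
  ring_of <- rep(1:3, each = 11)
  sec_cent <- (seq_len(72) - 0.5) * 5
  for (b in 1:2) {
    for (seg in 1:16) {
      ring <- if (seg <= 6) 1L else if (seg <= 12) 2L else 3L
      segs <- aha_segment(sec_cent, ring)
      lay <- which(ring_of == ring)
      cols <- which(segs == seg)
      cnt <- g$voxel_count[b, lay, cols]
      mu <- g$mean_ecv[b, lay, cols]
      expected <- sum(mu[cnt > 0] * cnt[cnt > 0]) / sum(cnt)
      got <- a$mean_ecv[a$segment == seg & a$band == c("subendo", "subepi")[b]]
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})

test_that("compartment CSV export has one row per cell", {
  ph <- generate_phantom(coarse_spec())
  ecv <- phantom_ecv(ph)
  g <- build_compartments(ecv, ph$truth$myocardium_mask, ph$truth$geometry)
  csv <- file.path(tempdir(), "compartments.csv")
  compartments_to_csv(g, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 7344)
  expect_equal(names(df), c("depth_layer", "layer", "sector",
                            "mean_ecv_percent", "voxel_count"))
  expect_equal(sum(df$voxel_count), sum(g$voxel_count))
  expect_equal(df$mean_ecv_percent[df$depth_layer == 2 & df$layer == 17 &
                                     df$sector == 36],
               100 * g$mean_ecv[2, 17, 36])
})
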