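test_that("magnification correction follows the axial-length relation", {
  expect_equal(magnification_correction(23.95, 23.95), 1.0)
  expect_equal(magnification_correction(23.5, 23.5), 1.0)
  expect_equal(magnification_correction(26.0, 23.95),
               (0.01306 * 24.18) / (0.01306 * 22.13), tolerance = 1e-10)
  expect_equal(round(magnification_correction(26.0, 23.95), 4), 1.0926)
  expect_error(magnification_correction(14), "plausible range")
  expect_error(magnification_correction(36), "plausible range")
})

test_that("gradient cost localizes step edges by polarity", {
  img <- matrix(10, 40, 12)
  img[25:40, ] <- 200                      # dark above, bright below
  cost <- gradient_cost(img, "dark_to_bright", smooth_sigma = 0)
  expect_true(all(apply(cost, 2, which.min) == 25))
  expect_true(all(cost > 0 & cost <= 1))
  # inverting the image swaps the polarities' cost rasters; use an image
  # carrying both edge polarities so neither raster is degenerate
  img2 <- matrix(10, 40, 12)
  img2[15:24, ] <- 200
  c1 <- gradient_cost(img2, "bright_to_dark", smooth_sigma = 0)
  c2 <- gradient_cost(max(img2) - img2, "dark_to_bright",
                      smooth_sigma = 0)
  expect_equal(c1, c2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(gradient_cost(matrix(7, 10, 10)), "uniform")
})

test_that("trace_boundary follows a flat zero-cost row exactly", {
  cost <- matrix(1, 30, 20)
  cost[17, ] <- 0
  expect_identical(trace_boundary(cost), rep(17L, 20))
})

test_that("trace_boundary equals exhaustive enumeration on random instances", {
  set.seed(1203)
  for (i in 1:25) {
    n <- sample(4:12, 1); m <- sample(3:8, 1)
    ms <- sample(1:3, 1)
    cost <- matrix(runif(n * m), n, m)
    expect_identical(as.integer(trace_boundary(cost, max_step = ms)),
                     as.integer(brute_force_path(cost, ms)))
  }
})

test_that("trace_boundary validates its search band", {
  cost <- matrix(runif(50), 10, 5)
  expect_error(trace_boundary(cost, band = rbind(rep(8, 5), rep(3, 5))),
               "empty search band")
  band <- rbind(c(1, 9, 1, 1, 1), c(2, 10, 2, 2, 2))
  expect_error(trace_boundary(cost, band = band, max_step = 2),
               "exceeds max_step")
})

test_that("nine boundaries are recovered on phantoms and never cross", {
  clean <- make_bscan_phantom(shape = "flat", speckle = 0, blur_sigma = 0)
  bs <- segment_boundaries(clean$bscan)
  expect_identical(bs$boundaries, clean$truth)
  for (cfg in list(list(shape = "sine", speckle = 0.18, seed = 7),
                   list(shape = "pit", speckle = 0.10, seed = 3))) {
    ph <- make_bscan_phantom(shape = cfg$shape, amplitude = 8,
                             speckle = cfg$speckle, blur_sigma = 1,
                             seed = cfg$seed)
    bs <- segment_boundaries(ph$bscan)
    mae <- rowMeans(abs(bs$boundaries - ph$truth))
    expect_true(all(mae <= 2))
    expect_true(all(diff(bs$boundaries) >= 0))
  }
})

test_that("layer thickness is boundary subtraction times axial scale", {
  B <- matrix(10L, 9, 6)
  B[3, ] <- 30L
  expect_equal(layer_thickness(B, 1, 3, axial_scale = 3.1),
               rep(62, 6))
  expect_equal(layer_thickness(B, 1, 2, axial_scale = 3.1), rep(0, 6))
  ph <- make_bscan_phantom(shape = "sine", speckle = 0.1, blur_sigma = 1)
  bs <- segment_boundaries(ph$bscan)
  nfl <- layer_thickness(bs, 1, 2)
  gclipl <- layer_thickness(bs, 2, 3)
  gcc <- layer_thickness(bs, 1, 3)
  expect_identical(nfl + gclipl, gcc)
})

test_that("radial profiles interpolate onto the fovea-centered map", {
  g <- fovea_grid(201, 201, 3 / 201)
  angles <- seq(0, 170, by = 10)
  # constant profiles reproduce the constant
  prof <- matrix(95, 18, 257)
  map <- radial_to_map(prof, angles, g, lateral_scale_um = 12)
  expect_true(all(abs(map$values - 95) < 1e-9, na.rm = TRUE))
  expect_true(any(!is.na(map$values)))
  # angle-independent linear-in-radius profiles match the closed form
  mid <- 129
  lin <- t(vapply(1:18, function(i) 50 + 20 * abs((1:257) - mid) * 12 / 1000,
                  numeric(257)))
  map2 <- radial_to_map(lin, angles, g, lateral_scale_um = 12)
  r_mm <- maculaquant:::grid_radius_mm(g)
  expected <- 50 + 20 * r_mm
  ok <- !is.na(map2$values)
  expect_lt(max(abs(map2$values - expected)[ok]), 0.5)
  # a pixel on a scanned meridian takes that profile's value
  prof3 <- matrix(rep(seq(40, 210, by = 10), 257), 18, 257)
  map3 <- radial_to_map(prof3, angles, g, lateral_scale_um = 12)
  ctr <- 101
  expect_equal(map3$values[ctr - 30, ctr], prof3[1, mid + 30])
})

test_that("regional thickness means honour masks and missing data", {
  g <- fovea_grid(304, 304, 3 / 304, laterality = "OD")
  masks <- c(list(C = make_annulus_mask(g, 0, 0.6, "C"),
                  TAZ = make_annulus_mask(g, 0.6, 2.5, "TAZ")),
             make_sector_masks(g, 0.6, 2.5))
  const <- structure(list(values = matrix(95.2, 304, 304), grid = g,
                          layer_name = "GCC"), class = "thickness_map")
  tbl <- regional_mean_thickness(const, masks)
  expect_true(all(abs(tbl$mean_um - 95.2) < 0.5))
  # purely radial map -> all four sector means equal
  radial <- structure(list(values = 60 + 30 * maculaquant:::grid_radius_mm(g),
                           grid = g, layer_name = "GCC"),
                      class = "thickness_map")
  tbl2 <- regional_mean_thickness(radial, masks)
  sect <- tbl2$mean_um[tbl2$region %in% c("S", "T", "I", "N")]
  expect_lt(diff(range(sect)), 0.2)
  # fully missing region errors
  missing_map <- structure(list(values = matrix(NA_real_, 304, 304),
                                grid = g, layer_name = "GCC"),
                           class = "thickness_map")
  expect_error(regional_mean_thickness(missing_map, masks["C"]),
               "no defined thickness")
})

test_that("an eye's regional thicknesses are recovered end to end", {
  scans <- make_eye_phantom(seed = 2)
  bscans <- lapply(scans, `[[`, "bscan")
  th <- quantify_thickness(bscans, laterality = "OD")
  g <- fovea_grid(304, 304, 3 / 304, laterality = "OD")
  masks <- c(list(C = make_annulus_mask(g, 0, 0.6, "C"),
                  TAZ = make_annulus_mask(g, 0.6, 2.5, "TAZ")),
             make_sector_masks(g, 0.6, 2.5))
  pairs <- maculaquant:::layer_boundary_pairs()
  angles <- seq(0, 170, by = 10)
  truth <- purrr::map_dfr(names(pairs), function(ly) {
    prof <- t(vapply(scans, function(s)
      (s$truth[pairs[[ly]][2], ] - s$truth[pairs[[ly]][1], ]) * 3,
      numeric(ncol(scans[[1]]$truth))))
    regional_mean_thickness(
      radial_to_map(prof, angles, g, 12, layer_name = ly), masks)
  })
  cmp <- dplyr::inner_join(th, truth, by = c("layer", "region"),
                           suffix = c("_est", "_true"))
  expect_equal(nrow(cmp), 30)
  expect_lt(max(abs(cmp$mean_um_est - cmp$mean_um_true)), 3)
  # GCC = NFL + GCL+IPL at regional-mean level, to machine precision
  wide <- tidyr::pivot_wider(th, id_cols = "region",
                             names_from = "layer",
                             values_from = "mean_um")
  expect_equal(wide$GCC, wide$NFL + wide$`GCL+IPL`, tolerance = 1e-12)
})
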