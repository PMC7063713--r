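test_that("annulus and disk masks match closed-form areas", {
  g <- fovea_grid(1024, 1024, 3 / 1024, laterality = "OD")
  taz <- make_annulus_mask(g, 0.60, 2.50)
  area <- sum(taz$pixels) * g$mm_per_pixel^2
  expect_lt(abs(area - pi * (1.25^2 - 0.30^2)) / (pi * (1.25^2 - 0.30^2)),
            0.01)
  disk <- make_annulus_mask(g, 0, 0.60)
  area_c <- sum(disk$pixels) * g$mm_per_pixel^2
  expect_lt(abs(area_c - pi * 0.30^2) / (pi * 0.30^2), 0.02)
})

test_that("degenerate or oversized annuli are rejected", {
  g <- fovea_grid(304, 304, 3 / 304)
  expect_error(make_annulus_mask(g, 1.0, 1.0), "inner_d < outer_d")
  expect_error(make_annulus_mask(g, 0, 4.0), "beyond the image")
  expect_error(fovea_grid(100, 100, 0.01, center_row = 200),
               "outside the image")
})

test_that("ring series partitions the TAZ exactly with isometric radii", {
  g <- fovea_grid(1024, 1024, 3 / 1024)
  rings <- make_ring_series(g)
  taz <- make_annulus_mask(g, 0.60, 2.50)
  union <- Reduce(`|`, lapply(rings, function(m) m$pixels))
  expect_identical(union, taz$pixels)
  n_overlap <- sum(Reduce(`+`, lapply(rings, function(m) m$pixels)) > 1)
  expect_identical(n_overlap, 0L)
  c1_area <- sum(rings$C1$pixels) * g$mm_per_pixel^2
  expect_lt(abs(c1_area - pi * (0.46^2 - 0.30^2)) /
              (pi * (0.46^2 - 0.30^2)), 0.02)
  d <- unname(region_diameters_mm[c("C", paste0("C", 1:6))])
  increments <- diff(d) / 2
  expect_true(all(increments >= 0.1549 & increments <= 0.1651))
})

test_that("sector masks partition the annulus and respect laterality", {
  g_od <- fovea_grid(512, 512, 3 / 512, laterality = "OD")
  g_os <- fovea_grid(512, 512, 3 / 512, laterality = "OS")
  s_od <- make_sector_masks(g_od, 0.6, 2.5)
  s_os <- make_sector_masks(g_os, 0.6, 2.5)
  ann <- make_annulus_mask(g_od, 0.6, 2.5)
  total <- Reduce(`+`, lapply(s_od, function(m) m$pixels))
  expect_identical(total == 1, ann$pixels)      # exact partition
  areas <- vapply(s_od, function(m) sum(m$pixels), integer(1))
  expect_true(all(abs(areas - mean(areas)) / mean(areas) < 0.01))
  # OD <-> OS swaps temporal and nasal, leaves superior/inferior alone
  expect_identical(s_od$S$pixels, s_os$S$pixels)
  expect_identical(s_od$I$pixels, s_os$I$pixels)
  expect_identical(s_od$T$pixels, s_os$N$pixels)
  expect_identical(s_od$N$pixels, s_os$T$pixels)
  # a pixel straight above the center at 0.9 mm radius is superior only
  r_px <- round(0.9 / g_od$mm_per_pixel)
  ctr <- round(c(g_od$center_row, g_od$center_col)) + 1
  hits <- vapply(s_od, function(m) m$pixels[ctr[1] - r_px, ctr[2]],
                 logical(1))
  expect_identical(unname(hits), c(TRUE, FALSE, FALSE, FALSE))
  g_na <- fovea_grid(512, 512, 3 / 512)
  expect_error(make_sector_masks(g_na, 0.6, 2.5), "laterality")
})

test_that("mask areas converge to analytic areas with resolution", {
  true_area <- pi * (1.25^2 - 0.30^2)
  rel_err <- vapply(c(304, 1024), function(n) {
    g <- fovea_grid(n, n, 3 / n)
    m <- make_annulus_mask(g, 0.60, 2.50)
    abs(sum(m$pixels) * g$mm_per_pixel^2 - true_area) / true_area
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.01)
})

test_that("masks tolerate fractional-pixel center shifts", {
  g0 <- fovea_grid(512, 512, 3 / 512)
  a0 <- sum(make_annulus_mask(g0, 0.60, 2.50)$pixels)
  for (shift in list(c(0.5, 0), c(0, 0.5), c(0.35, -0.35))) {
    g1 <- fovea_grid(512, 512, 3 / 512,
                     center_row = 255.5 + shift[1],
                     center_col = 255.5 + shift[2])
    a1 <- sum(make_annulus_mask(g1, 0.60, 2.50)$pixels)
    expect_lt(abs(a1 - a0) / a0, 0.02)
  }
})

test_that("region table and PNG export work", {
  g <- fovea_grid(304, 304, 3 / 304, laterality = "OD")
  masks <- make_standard_masks(g)
  tbl <- region_table(masks)
  expect_setequal(tbl$name, c("C", "TAZ", paste0("C", 1:6),
                              "S", "T", "I", "N"))
  expect_true(all(tbl$area_mm2 > 0))
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(masks$TAZ, path)
  back <- png::readPNG(path)
  expect_identical(back > 0.5, masks$TAZ$pixels)
})
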