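#' Region diameters of the macular analysis grid
#'
#' The 2.5 mm macular analysis disk is split into a central 0.60 mm circle
#' (C, coinciding with the fixed foveal avascular zone disk), the total
#' annular zone (TAZ, 0.60--2.50 mm), six concentric annular rings C1--C6
#' with equally spaced diameters, and four 90-degree quadrant sectors
#' (S, T, I, N) bounded by the two 45-degree diagonals.
#'
#' @format Named numeric vector of outer diameters in mm.
#' @export
region_diameters_mm <- c(
  C = 0.60, C1 = 0.92, C2 = 1.23, C3 = 1.55,
  C4 = 1.87, C5 = 2.18, C6 = 2.50, TAZ = 2.50
)

new_region_mask <- function(grid, name, pixels) {
  structure(list(grid = grid, name = name, pixels = pixels),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d px, %.4f mm^2 on %dx%d grid\n",
              x$name, sum(x$pixels),
              sum(x$pixels) * x$grid$mm_per_pixel^2,
              x$grid$height, x$grid$width))
  invisible(x)
}

#' Annulus (or disk) mask around the fovea
#'
#' A pixel belongs to the annulus iff its center's distance to the fovea
#' center lies in the half-open radial interval `[inner_d/2, outer_d/2)`,
#' so consecutive rings partition exactly. `inner_d = 0` gives a disk.
#'
#' @param grid A [fovea_grid()].
#' @param inner_d,outer_d Inner and outer diameters in mm,
#'   `0 <= inner_d < outer_d`.
#' @param name Region label stored on the mask.
#' @return A `region_mask` (logical raster plus grid metadata).
#' @examples
#' g <- fovea_grid(1024, 1024, 3 / 1024)
#' m <- make_annulus_mask(g, 0.60, 2.50, name = "TAZ")
#' sum(m$pixels) * g$mm_per_pixel^2    # ~ pi * (1.25^2 - 0.30^2)
#' @export
make_annulus_mask <- function(grid, inner_d, outer_d, name = "annulus") {
  stopifnot(inherits(grid, "fovea_grid"))
  if (!(inner_d >= 0 && inner_d < outer_d)) {
    stop("need 0 <= inner_d < outer_d (got ", inner_d, ", ", outer_d, ")",
         call. = FALSE)
  }
  half_mm <- outer_d / 2
  room_mm <- grid$mm_per_pixel * min(
    grid$center_row, grid$center_col,
    grid$height - 1 - grid$center_row, grid$width - 1 - grid$center_col)
  if (half_mm > room_mm + grid$mm_per_pixel / 2) {
    stop(sprintf(
      "annulus outer radius %.3f mm extends %.3f mm beyond the image",
      half_mm, half_mm - room_mm), call. = FALSE)
  }
  r <- grid_radius_mm(grid)
  new_region_mask(grid, name, r >= inner_d / 2 & r < outer_d / 2)
}

#' Six concentric annular ring masks C1--C6
#'
#' Ring k spans diameters `d[k-1]` to `d[k]` with
#' `d = (0.60, 0.92, 1.23, 1.55, 1.87, 2.18, 2.50)` mm; the rings are
#' pairwise disjoint and their union is exactly the TAZ mask.
#'
#' @inheritParams make_annulus_mask
#' @return Named list of six `region_mask` objects `C1..C6`.
#' @export
make_ring_series <- function(grid) {
  d <- unname(region_diameters_mm[c("C", paste0("C", 1:6))])
  masks <- lapply(1:6, function(k) {
    make_annulus_mask(grid, d[k], d[k + 1], name = paste0("C", k))
  })
  names(masks) <- paste0("C", 1:6)
  masks
}

#' Quadrant sector masks S, T, I, N
#'
#' Partitions an annulus into four 90-degree sectors bounded by the two
#' 45-degree diagonals through the fovea center: superior (up), inferior
#' (down), and temporal/nasal assigned from eye laterality. En face images
#' are assumed displayed in fundus orientation; `temporal_side` gives the
#' image side of the temporal retina for a right eye (`"left"` by default,
#' mirrored for OS).
#'
#' @inheritParams make_annulus_mask
#' @param temporal_side `"left"` or `"right"`: image side of the temporal
#'   sector for an OD eye (OS is mirrored).
#' @return Named list of four `region_mask` objects `S`, `T`, `I`, `N`.
#' @export
make_sector_masks <- function(grid, inner_d, outer_d,
                              temporal_side = c("left", "right")) {
  temporal_side <- match.arg(temporal_side)
  if (is.na(grid$laterality)) {
    stop("sector masks need grid laterality (OD/OS) to assign T and N",
         call. = FALSE)
  }
  ann <- make_annulus_mask(grid, inner_d, outer_d)$pixels
  ang <- grid_angle_deg(grid)
  up    <- ann & (ang >= 315 | ang < 45)
  right <- ann & (ang >= 45  & ang < 135)
  down  <- ann & (ang >= 135 & ang < 225)
  left  <- ann & (ang >= 225 & ang < 315)
  od_temporal_left <- (temporal_side == "left")
  t_is_left <- if (grid$laterality == "OD") od_temporal_left else !od_temporal_left
  masks <- list(
    S = new_region_mask(grid, "S", up),
    T = new_region_mask(grid, "T", if (t_is_left) left else right),
    I = new_region_mask(grid, "I", down),
    N = new_region_mask(grid, "N", if (t_is_left) right else left)
  )
  masks
}

#' Standard macular region masks
#'
#' Convenience builder for the full region set used by both the thickness
#' and the capillary-density analyses: `C` (0.60 mm disk), `TAZ`
#' (0.60--2.50 mm), rings `C1..C6` and sectors `S,T,I,N` on the TAZ annulus.
#'
#' @inheritParams make_sector_masks
#' @return Named list of `region_mask` objects.
#' @export
make_standard_masks <- function(grid, temporal_side = "left") {
  c(
    list(C   = make_annulus_mask(grid, 0, region_diameters_mm[["C"]], "C"),
         TAZ = make_annulus_mask(grid, region_diameters_mm[["C"]],
                                 region_diameters_mm[["TAZ"]], "TAZ")),
    make_ring_series(grid),
    make_sector_masks(grid, region_diameters_mm[["C"]],
                      region_diameters_mm[["TAZ"]],
                      temporal_side = temporal_side)
  )
}

#' Tabulate region masks
#'
#' @param masks Named list of `region_mask` objects.
#' @return Tibble with one row per region: name, pixel count and area.
#' @export
region_table <- function(masks) {
  tibble::tibble(
    name = names(masks),
    pixel_count = vapply(masks, function(m) sum(m$pixels), integer(1)),
    area_mm2 = vapply(masks, function(m)
      sum(m$pixels) * m$grid$mm_per_pixel^2, numeric(1))
  )
}

#' Write a region mask as an 8-bit PNG (0/255) for inspection
#'
#' @param mask A `region_mask`.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}
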