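#' Fovea-centered raster grid
#'
#' The common coordinate frame for all regional analysis: a square (or
#' rectangular) pixel raster with an isotropic millimetre scale and a
#' fovea center that may sit between pixel centers. En face angiograms use
#' a 3 x 3 mm field rendered at 304 px (device native) or 1024 px (after
#' bicubic upsampling); thickness maps use the same frame.
#'
#' Coordinates are 0-based (row, col) at pixel centers, row 0 at the top.
#'
#' @param height,width Raster dimensions in pixels.
#' @param mm_per_pixel Isotropic pixel pitch in mm.
#' @param center_row,center_col Fovea center in 0-based pixel coordinates
#'   (fractional values allowed). Default: the image center.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye); `NA` allowed
#'   until sector masks are requested.
#' @return An object of class `fovea_grid`.
#' @examples
#' g <- fovea_grid(1024, 1024, mm_per_pixel = 3 / 1024, laterality = "OD")
#' g
#' @export
fovea_grid <- function(height, width, mm_per_pixel,
                       center_row = (height - 1) / 2,
                       center_col = (width - 1) / 2,
                       laterality = NA_character_) {
  stopifnot(height > 0, width > 0, mm_per_pixel > 0)
  if (center_row < 0 || center_row > height - 1 ||
      center_col < 0 || center_col > width - 1) {
    stop("fovea center (", center_row, ", ", center_col,
         ") lies outside the image bounds", call. = FALSE)
  }
  if (!is.na(laterality) && !laterality %in% c("OD", "OS")) {
    stop("laterality must be 'OD', 'OS' or NA", call. = FALSE)
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         mm_per_pixel = mm_per_pixel,
         center_row = center_row, center_col = center_col,
         laterality = laterality),
    class = "fovea_grid"
  )
}

#' @export
print.fovea_grid <- function(x, ...) {
  cat(sprintf(
    "<fovea_grid> %d x %d px, %.4f mm/px (%.2f x %.2f mm), center (%.1f, %.1f), %s\n",
    x$height, x$width, x$mm_per_pixel,
    x$height * x$mm_per_pixel, x$width * x$mm_per_pixel,
    x$center_row, x$center_col,
    if (is.na(x$laterality)) "laterality NA" else x$laterality))
  invisible(x)
}

# radial distance (mm) of every pixel center from the fovea center,
# returned as a height x width matrix
grid_radius_mm <- function(grid) {
  dr <- (seq_len(grid$height) - 1) - grid$center_row
  dc <- (seq_len(grid$width) - 1) - grid$center_col
  sqrt(outer(dr^2, dc^2, "+")) * grid$mm_per_pixel
}

# polar angle (degrees in [0, 360)) with 0 = image "up" (decreasing row),
# increasing clockwise on the displayed image
grid_angle_deg <- function(grid) {
  dr <- (seq_len(grid$height) - 1) - grid$center_row
  dc <- (seq_len(grid$width) - 1) - grid$center_col
  ang <- atan2(outer(rep(1, grid$height), dc),
               outer(-dr, rep(1, grid$width))) * 180 / pi
  (ang + 360) %% 360
}
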