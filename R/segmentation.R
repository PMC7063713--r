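# Intra-retinal layer segmentation: nine boundaries per B-scan traced by
# a gradient-cost shortest path, thickness by boundary subtraction, and
# radial-scan interpolation onto a fovea-centered thickness map.

#' B-scan container
#'
#' @param intensity Numeric matrix, rows = depth (top = vitreous),
#'   cols = lateral position.
#' @param axial_scale Axial sampling, micrometres per pixel.
#' @param lateral_scale Nominal lateral sampling, micrometres per pixel
#'   (before magnification correction).
#' @param meridian_angle Scan meridian in degrees (0 = horizontal).
#' @param eye_axial_length Axial length of the imaged eye in mm.
#' @return Object of class `bscan`.
#' @export
bscan <- function(intensity, axial_scale, lateral_scale,
                  meridian_angle = 0, eye_axial_length = 23.95) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)),
            axial_scale > 0, lateral_scale > 0)
  structure(list(intensity = intensity, axial_scale = axial_scale,
                 lateral_scale = lateral_scale,
                 meridian_angle = meridian_angle,
                 eye_axial_length = eye_axial_length),
            class = "bscan")
}

#' Lateral magnification correction from axial length
#'
#' Ocular magnification scales with Bennett's abbreviated axial-length
#' relation q(AL) = 0.01306 (AL - 1.82) mm/deg. The returned factor
#' q(AL)/q(reference) multiplies the nominal lateral scale so transverse
#' distances are comparable across eyes of different lengths.
#'
#' @param eye_axial_length Axial length in mm (must lie in (15, 35)).
#' @param reference_length Reference axial length in mm (default 23.95,
#'   the scale assumed by the device).
#' @return Dimensionless scale factor.
#' @examples
#' magnification_correction(26.0, 23.95)  # 1.0926
#' @export
magnification_correction <- function(eye_axial_length,
                                     reference_length = 23.95) {
  if (eye_axial_length <= 15 || eye_axial_length >= 35) {
    stop("axial length ", eye_axial_length,
         " mm outside the plausible range (15, 35)", call. = FALSE)
  }
  q <- function(al) 0.01306 * (al - 1.82)
  q(eye_axial_length) / q(reference_length)
}

#' Gradient cost image for boundary tracing
#'
#' Low cost where the signed vertical (depth) intensity gradient matches
#' the requested polarity: `dark_to_bright` boundaries have intensity
#' increasing with depth, `bright_to_dark` decreasing. The cost is
#' normalized to (0, 1] and strictly positive so cumulative path cost is
#' monotone in path length.
#'
#' @param x A [bscan()] or numeric matrix.
#' @param polarity `"dark_to_bright"` or `"bright_to_dark"`.
#' @param smooth_sigma Gaussian pre-smoothing SD in px (0 = none).
#' @return Numeric cost matrix with attribute `flat` set TRUE (with a
#'   warning) when the image carries no gradient at all.
#' @export
gradient_cost <- function(x, polarity = c("dark_to_bright", "bright_to_dark"),
                          smooth_sigma = 1) {
  polarity <- match.arg(polarity)
  img <- if (inherits(x, "bscan")) x$intensity else x
  stopifnot(is.matrix(img))
  img <- gaussian_blur(img, smooth_sigma)
  n <- nrow(img)
  # backward-difference vertical gradient: a step between rows r-1 and r
  # yields its full magnitude at row r (the first row of the new layer),
  # so boundary rows are localized without the half-pixel bias of a
  # central difference
  g <- img - img[c(1, 1:(n - 1)), , drop = FALSE]
  if (polarity == "bright_to_dark") g <- -g
  g[g < 0] <- 0
  gmax <- max(g)
  eps <- 1e-6
  if (gmax == 0) {
    warning("image has no gradient matching the requested polarity; ",
            "cost is uniform")
    cost <- matrix(1, nrow(img), ncol(img))
    attr(cost, "flat") <- TRUE
    return(cost)
  }
  cost <- 1 - g / gmax * (1 - eps)
  attr(cost, "flat") <- FALSE
  cost
}

#' Minimum-cost boundary trace across columns
#'
#' Finds the left-to-right path with one node per column, vertical moves
#' of at most `max_step` rows between adjacent columns, minimizing the
#' summed cost, restricted to a per-column search band. Solved by
#' column-wise dynamic programming (equivalent to Dijkstra on the layered
#' DAG); ties break toward the smaller row index, making the result
#' bit-reproducible.
#'
#' @param cost Numeric cost matrix.
#' @param band Integer matrix or vector pair: either a 2 x ncol matrix of
#'   (top, bottom) row limits per column, or `c(top, bottom)` applied to
#'   all columns. 1-based, inclusive.
#' @param max_step Maximum row change between adjacent columns (>= 1).
#' @return Integer vector: row index of the path at each column.
#' @export
trace_boundary <- function(cost, band = c(1L, nrow(cost)), max_step = 2L) {
  stopifnot(is.matrix(cost), max_step >= 1)
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(dim(band))) band <- matrix(as.integer(band), 2, m)
  band[1, ] <- pmax(band[1, ], 1L)
  band[2, ] <- pmin(band[2, ], n)
  if (any(band[1, ] > band[2, ])) {
    stop("empty search band in column ", which(band[1, ] > band[2, ])[1],
         call. = FALSE)
  }
  # feasibility: consecutive bands must be reachable within max_step
  for (j in seq_len(m - 1)) {
    if (band[1, j + 1] > band[2, j] + max_step ||
        band[2, j + 1] < band[1, j] - max_step) {
      stop("search band jump between columns ", j, " and ", j + 1,
           " exceeds max_step = ", max_step, call. = FALSE)
    }
  }
  k <- as.integer(max_step)
  D <- matrix(Inf, n, m)       # cumulative cost
  P <- matrix(0L, n, m)        # predecessor row
  r0 <- band[1, 1]:band[2, 1]
  D[r0, 1] <- cost[r0, 1]
  shifts <- -k:k               # ascending: ties resolve to smaller row
  for (j in 2:m) {
    rows <- band[1, j]:band[2, j]
    prev_pad <- c(rep(Inf, k), D[, j - 1], rep(Inf, k))
    cand <- vapply(shifts, function(s) prev_pad[rows + s + k],
                   numeric(length(rows)))
    cand <- matrix(cand, nrow = length(rows))
    best <- max.col(-cand, ties.method = "first")
    bestv <- cand[cbind(seq_along(rows), best)]
    ok <- is.finite(bestv)
    D[rows[ok], j] <- bestv[ok] + cost[rows[ok], j]
    P[rows[ok], j] <- rows[ok] + shifts[best[ok]]
  }
  path <- integer(m)
  last <- band[1, m]:band[2, m]
  if (!any(is.finite(D[last, m]))) {
    stop("no feasible path through the search band", call. = FALSE)
  }
  path[m] <- last[which.min(D[last, m])]
  for (j in m:2) path[j - 1] <- P[path[j], j]
  path
}

#' Default boundary tracing schedule
#'
#' Order, gradient polarity, and the band anchors used by
#' [segment_boundaries()]. Boundaries are numbered 1 (inner limiting
#' membrane) to 9 (outer retinal boundary); the most salient interfaces
#' (1, 9, then the outer-plexiform transition 5) are traced first and each
#' later search is confined between its already-traced neighbours.
#'
#' @return Tibble with columns `boundary`, `polarity`, `upper`, `lower`
#'   (anchor boundary indices, 0 = image top, 10 = image bottom).
#' @export
segmentation_schedule <- function() {
  tibble::tribble(
    ~boundary, ~polarity,        ~upper, ~lower,
    1L, "dark_to_bright", 0L, 10L,
    9L, "bright_to_dark", 1L, 10L,
    5L, "bright_to_dark", 1L, 9L,
    2L, "bright_to_dark", 1L, 5L,
    3L, "bright_to_dark", 2L, 5L,
    4L, "dark_to_bright", 3L, 5L,
    8L, "dark_to_bright", 5L, 9L,
    7L, "dark_to_bright", 5L, 8L,
    6L, "dark_to_bright", 5L, 7L
  )
}

#' Segment the nine intra-retinal boundaries of a B-scan
#'
#' Sequential gradient-cost shortest-path tracing following
#' [segmentation_schedule()]: the inner limiting membrane and the outer
#' retinal boundary first, then interior boundaries, each restricted to
#' the band between its already-found neighbours (with a one-pixel
#' margin), so the non-crossing invariant holds by construction.
#'
#' @param bscan A [bscan()].
#' @param max_step Per-column step bound for [trace_boundary()].
#' @param smooth_sigma Pre-smoothing SD passed to [gradient_cost()].
#' @param band_margin Pixels excluded on each side of an already-traced
#'   neighbour when banding the next search, so the neighbour's
#'   blur-spread edge cannot capture the path. Default scales with the
#'   smoothing kernel (`3 * smooth_sigma`, at least 2).
#' @param schedule Tracing schedule tibble; see [segmentation_schedule()].
#' @return Object of class `boundary_set`: integer matrix `9 x ncol`
#'   (row = boundary index, inner to outer) plus the axial scale.
#' @export
segment_boundaries <- function(bscan, max_step = 2L, smooth_sigma = 1,
                               band_margin = NULL,
                               schedule = segmentation_schedule()) {
  stopifnot(inherits(bscan, "bscan"))
  if (is.null(band_margin)) {
    band_margin <- max(2L, as.integer(ceiling(3 * smooth_sigma)))
  }
  img <- bscan$intensity
  n <- nrow(img); m <- ncol(img)
  costs <- list(
    dark_to_bright = gradient_cost(img, "dark_to_bright", smooth_sigma),
    bright_to_dark = gradient_cost(img, "bright_to_dark", smooth_sigma)
  )
  found <- matrix(NA_integer_, 9, m)
  anchor <- function(idx, side) {
    if (idx == 0L) rep(1L, m)
    else if (idx == 10L) rep(n, m)
    else found[idx, ] + if (side == "upper") band_margin else -band_margin
  }
  for (i in seq_len(nrow(schedule))) {
    b <- schedule$boundary[i]
    band <- rbind(anchor(schedule$upper[i], "upper"),
                  anchor(schedule$lower[i], "lower"))
    band[2, ] <- pmax(band[2, ], band[1, ])  # allow touching layers
    path <- tryCatch(
      trace_boundary(costs[[schedule$polarity[i]]], band, max_step),
      error = function(e) stop("boundary ", b, " trace failed: ",
                               conditionMessage(e), call. = FALSE))
    found[b, ] <- path
  }
  # enforce ordering exactly (bands allow equality; rounding guard)
  for (b in 2:9) found[b, ] <- pmax(found[b, ], found[b - 1, ])
  structure(list(boundaries = found, axial_scale = bscan$axial_scale,
                 lateral_scale = bscan$lateral_scale,
                 meridian_angle = bscan$meridian_angle),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set> 9 boundaries x %d columns, axial %.2f um/px\n",
              ncol(x$boundaries), x$axial_scale))
  invisible(x)
}

#' Layer thickness profile from a boundary pair
#'
#' @param boundaries A `boundary_set` (from [segment_boundaries()]) or a
#'   9 x m integer matrix.
#' @param upper_index,lower_index Boundary indices, `upper < lower`.
#' @param axial_scale Micrometres per pixel; defaults to the value stored
#'   on the boundary set.
#' @return Numeric vector: thickness in micrometres per column.
#' @export
layer_thickness <- function(boundaries, upper_index, lower_index,
                            axial_scale = NULL) {
  B <- if (inherits(boundaries, "boundary_set")) boundaries$boundaries else boundaries
  if (is.null(axial_scale)) {
    stopifnot(inherits(boundaries, "boundary_set"))
    axial_scale <- boundaries$axial_scale
  }
  stopifnot(upper_index < lower_index)
  (B[lower_index, ] - B[upper_index, ]) * axial_scale
}

# layer definitions reported by the pipeline: boundary index pairs
layer_boundary_pairs <- function() {
  list(
    "NFL"      = c(1L, 2L),
    "GCL+IPL"  = c(2L, 3L),
    "GCC"      = c(1L, 3L),
    "INL+ORL"  = c(3L, 9L),
    "TOTAL"    = c(1L, 9L)
  )
}

#' Interpolate radial thickness profiles onto a fovea-centered map
#'
#' The device acquires radial B-scans on evenly spaced meridians through
#' the fovea; each scan yields a thickness profile whose midpoint is the
#' fovea. A map pixel at radius r and angle theta is interpolated linearly
#' between the two angularly adjacent half-meridian profiles, and linearly
#' in radius along each. Pixels beyond the profile extent are NA.
#'
#' @param profiles Numeric matrix, one row per meridian, columns = lateral
#'   samples (fovea at the midpoint `(ncol+1)/2`).
#' @param angles Meridian angles in degrees, evenly spaced over 180.
#' @param grid A [fovea_grid()] for the output map.
#' @param lateral_scale_um Lateral sampling of the profiles in um/px.
#' @param layer_name Stored on the result.
#' @return Object of class `thickness_map`: numeric matrix (um) + grid.
#' @export
radial_to_map <- function(profiles, angles, grid, lateral_scale_um,
                          layer_name = "GCC") {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(angles))
  n_mer <- nrow(profiles)
  mid <- (ncol(profiles) + 1) / 2
  max_r_px <- ncol(profiles) - mid  # samples available on each side
  r_mm <- grid_radius_mm(grid)
  th_deg <- grid_angle_deg(grid)
  r_px <- r_mm * 1000 / lateral_scale_um
  # direction angle -> (meridian angle in [0,180), side +1/-1)
  side <- ifelse(th_deg < 180, 1, -1)
  mer_ang <- th_deg %% 180
  step <- 180 / n_mer
  # fractional meridian index (angles assumed sorted ascending from angles[1])
  fidx <- (mer_ang - angles[1]) / step
  i0 <- floor(fidx)
  w <- fidx - i0
  idx_a <- (as.integer(i0) %% n_mer) + 1L
  idx_b <- (as.integer(i0 + 1) %% n_mer) + 1L
  # crossing 180 flips the half-meridian side for the upper neighbour
  wrap_b <- (i0 + 1) >= n_mer
  sample_profile <- function(idx, sgn) {
    pos <- mid + sgn * r_px
    p0 <- floor(pos); fr <- pos - p0
    ok <- p0 >= 1 & p0 + 1 <= ncol(profiles)
    out <- matrix(NA_real_, nrow(pos), ncol(pos))
    flat_idx <- cbind(as.vector(idx), as.vector(p0))
    flat_idx2 <- cbind(as.vector(idx), as.vector(p0) + 1)
    v0 <- v1 <- rep(NA_real_, length(pos))
    sel <- as.vector(ok)
    v0[sel] <- profiles[flat_idx[sel, , drop = FALSE]]
    v1[sel] <- profiles[flat_idx2[sel, , drop = FALSE]]
    out[] <- (1 - as.vector(fr)) * v0 + as.vector(fr) * v1
    out
  }
  side_a <- side
  side_b <- ifelse(wrap_b, -side, side)
  va <- sample_profile(matrix(idx_a, nrow(r_px), ncol(r_px)), side_a)
  vb <- sample_profile(matrix(idx_b, nrow(r_px), ncol(r_px)), side_b)
  vals <- (1 - w) * va + w * vb
  # exactly on a meridian: use that profile alone (also rescues NA partner)
  vals[w == 0] <- va[w == 0]
  vals[is.na(vals) & !is.na(va) & w < 0.5] <- va[is.na(vals) & !is.na(va) & w < 0.5]
  vals[is.na(vals) & !is.na(vb) & w >= 0.5] <- vb[is.na(vals) & !is.na(vb) & w >= 0.5]
  structure(list(values = vals, grid = grid, layer_name = layer_name),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s: %dx%d px, mean %.1f um (%.0f%% defined)\n",
              x$layer_name, nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Regional mean thickness
#'
#' Arithmetic mean of a thickness map over each region mask; pixels
#' outside the scanned extent (NA) are excluded, never imputed.
#'
#' @param map A `thickness_map`.
#' @param masks Named list of `region_mask` objects on the same grid.
#' @return Tibble: layer, region, mean_um, n_pixels.
#' @export
regional_mean_thickness <- function(map, masks) {
  stopifnot(inherits(map, "thickness_map"))
  purrr::map_dfr(names(masks), function(nm) {
    sel <- masks[[nm]]$pixels
    v <- map$values[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      stop("region ", nm, " has no defined thickness pixels", call. = FALSE)
    }
    tibble::tibble(layer = map$layer_name, region = nm,
                   mean_um = mean(v), n_pixels = length(v))
  })
}
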