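# Raster primitives shared by the segmentation and angiography modules.
# Images are plain numeric matrices indexed [row, col], row 1 at the top.

# Keys' bicubic convolution kernel (a = -0.5); reproduces constants and
# linear ramps exactly, which the tests rely on.
cubic_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  i2 <- s > 1 & s < 2
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

# 1-D bicubic interpolation weights from n_in samples to n_out, as an
# n_out x n_in matrix (edge-clamped); separable use: W_r %*% X %*% t(W_c).
bicubic_weights <- function(n_in, n_out) {
  # align pixel centers of the two grids
  x <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5  # 0-based input coord
  base <- floor(x)
  W <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), n_in - 1)          # clamp at borders
    w <- cubic_kernel(x - (base + k))
    W[cbind(seq_len(n_out), idx + 1)] <-
      W[cbind(seq_len(n_out), idx + 1)] + w
  }
  # normalize so rows sum to 1 (exact constant reproduction under clamping)
  W / rowSums(W)
}

#' Bicubic image resize
#'
#' Separable bicubic convolution (Keys kernel, a = -0.5) with edge
#' clamping, used to extend 304 x 304 en face angiograms to 1024 x 1024.
#'
#' @param img Numeric matrix.
#' @param height,width Output dimensions in pixels.
#' @return Numeric matrix of size `height` x `width`.
#' @export
bicubic_resize <- function(img, height, width) {
  stopifnot(is.matrix(img), height >= 1, width >= 1)
  Wr <- bicubic_weights(nrow(img), height)
  Wc <- bicubic_weights(ncol(img), width)
  Wr %*% img %*% t(Wc)
}

# Exact local mean over a (2h+1)^2 clipped square window via integral image.
box_mean <- function(img, half) {
  stopifnot(half >= 1)
  n <- nrow(img); m <- ncol(img)
  S <- matrix(0, n + 1, m + 1)
  S[-1, -1] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(n) - half, 1); r2 <- pmin(seq_len(n) + half, n)
  c1 <- pmax(seq_len(m) - half, 1); c2 <- pmin(seq_len(m) + half, m)
  sums <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

# Sobel gradients; returns list(gx = d/dcol, gy = d/drow)
sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as.matrix(EBImage::filter2(img, kx))
  gy <- as.matrix(EBImage::filter2(img, t(kx)))
  list(gx = gx, gy = gy)
}

#' Canny edge detector
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-level hysteresis linking (weak
#' edges kept only in connected components containing a strong edge).
#'
#' @param img Numeric matrix.
#' @param sigma Smoothing SD in px.
#' @param low,high Hysteresis thresholds as quantiles of the non-zero
#'   gradient magnitude.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 2, low = 0.7, high = 0.9) {
  sm <- gaussian_blur(img, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  n <- nrow(mag); m <- ncol(mag)
  # quantize direction to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang <- ((ang %% 180) + 180) %% 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4
  pad <- matrix(0, n + 2, m + 2); pad[2:(n + 1), 2:(m + 1)] <- mag
  shift <- function(dr, dc) pad[2:(n + 1) + dr, 2:(m + 1) + dc]
  nb <- list(
    list(shift(0, -1), shift(0, 1)),    # 0 deg: horizontal gradient
    list(shift(-1, 1), shift(1, -1)),   # 45
    list(shift(-1, 0), shift(1, 0)),    # 90
    list(shift(-1, -1), shift(1, 1))    # 135
  )
  keep <- matrix(FALSE, n, m)
  for (s in 0:3) {
    sel <- sector == s
    keep[sel] <- mag[sel] >= nb[[s + 1]][[1]][sel] &
      mag[sel] >= nb[[s + 1]][[2]][sel]
  }
  nz <- mag[mag > 0]
  if (length(nz) == 0) return(matrix(FALSE, n, m))
  th_low <- quantile(nz, low, names = FALSE)
  th_high <- quantile(nz, high, names = FALSE)
  strong <- keep & mag >= th_high
  weak <- keep & mag >= th_low
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak * 1)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  matrix(as.vector(lab) %in% keep_ids, n, m) & weak
}

# one step of the binary curve-smoothing operator used by the
# morphological level set: alternate open-close / close-open so neither
# erosion nor dilation bias accumulates across iterations
.mcv_smooth <- function(u, kern, it) {
  if (it %% 2 == 1) {
    v <- EBImage::opening(u * 1, kern)
    as.matrix(EBImage::closing(v, kern)) > 0.5
  } else {
    v <- EBImage::closing(u * 1, kern)
    as.matrix(EBImage::opening(v, kern)) > 0.5
  }
}

#' Morphological Chan--Vese level set
#'
#' Two-phase region-based active contour (piecewise-constant energy)
#' evolved with the morphological approximation: each iteration
#' reclassifies pixels by which region mean they are closer to, then
#' applies binary opening/closing as the curvature-smoothing step. Used to
#' delineate the foveal avascular zone against the perfused surround.
#'
#' With `band > 0` the exterior statistic is localized: the outside mean
#' is taken over a ring of that width just outside the current contour
#' rather than over the whole image, which anchors the contour to the
#' local interface when the exterior is textured rather than uniform.
#' With `anchor` set, only the region component connected to that (row,
#' col) pixel is kept and interior holes are filled each iteration, so
#' the result is a single simply connected region.
#'
#' @param img Numeric matrix (typically pre-smoothed).
#' @param init Logical matrix, initial interior.
#' @param max_iter Iteration cap.
#' @param smoothing Number of smoothing passes per iteration.
#' @param tol Stop when the fraction of pixels changing label falls below
#'   this value.
#' @param band Exterior-ring width in px (0 = global exterior mean).
#' @param anchor Optional (row, col) the region must contain.
#' @return Logical matrix: converged interior region.
#' @export
chan_vese <- function(img, init, max_iter = 60, smoothing = 1, tol = 1e-4,
                      band = 0, anchor = NULL) {
  stopifnot(identical(dim(img), dim(init)))
  u <- init
  kern <- EBImage::makeBrush(3, shape = "box")
  # the exterior ring starts half a band away from the contour so the
  # interface's own blurred transition does not pull its mean down
  gap <- as.integer(ceiling(band / 2))
  ring_kern <- if (band > 0) {
    EBImage::makeBrush(2 * (as.integer(band) + gap) + 1, shape = "disc")
  } else NULL
  gap_kern <- if (band > 0 && gap > 0) {
    EBImage::makeBrush(2 * gap + 1, shape = "disc")
  } else NULL
  for (it in seq_len(max_iter)) {
    if (!any(u) || all(u)) break
    c1 <- mean(img[u])
    c2 <- if (band > 0) {
      outer_d <- as.matrix(EBImage::dilate(u * 1, ring_kern)) > 0.5
      inner_d <- if (is.null(gap_kern)) u else
        as.matrix(EBImage::dilate(u * 1, gap_kern)) > 0.5
      ring <- outer_d & !inner_d
      if (any(ring)) mean(img[ring]) else mean(img[!u])
    } else mean(img[!u])
    u_new <- (img - c2)^2 > (img - c1)^2   # closer to interior mean
    for (s in seq_len(smoothing)) u_new <- .mcv_smooth(u_new, kern, it + s)
    if (!is.null(anchor) && any(u_new)) {
      lab <- EBImage::bwlabel(u_new * 1)
      al <- lab[anchor[1], anchor[2]]
      if (al == 0) {
        ids <- which(u_new, arr.ind = TRUE)
        near <- which.min((ids[, 1] - anchor[1])^2 +
                            (ids[, 2] - anchor[2])^2)
        al <- lab[ids[near, 1], ids[near, 2]]
      }
      u_new <- lab == al
      u_new <- as.matrix(EBImage::fillHull(u_new * 1)) > 0.5
    }
    changed <- mean(u_new != u)
    u <- u_new
    if (changed < tol) break
  }
  u
}

# separable sliding-window min/max filter over a (2*half+1)^2 square,
# computed with the logarithmic doubling trick (replicated borders)
running_extreme_1d <- function(M, half, op, along_rows = TRUE) {
  if (!along_rows) return(t(running_extreme_1d(t(M), half, op, TRUE)))
  n <- nrow(M)
  shift_rows <- function(X, k) {
    idx <- pmin(pmax(seq_len(n) + k, 1L), n)
    X[idx, , drop = FALSE]
  }
  # window radius r built as sums of powers of two
  out <- M
  covered <- 0L
  step <- 1L
  while (covered < half) {
    take <- min(step, half - covered)
    out <- op(op(out, shift_rows(out, take)), shift_rows(out, -take))
    covered <- covered + take
    step <- covered   # current 'out' aggregates a radius-'covered' window
  }
  out
}

box_min <- function(img, half) {
  running_extreme_1d(running_extreme_1d(img, half, pmin, TRUE),
                     half, pmin, FALSE)
}

box_max <- function(img, half) {
  running_extreme_1d(running_extreme_1d(img, half, pmax, TRUE),
                     half, pmax, FALSE)
}

# retain only connected components whose maximal inscribed width
# (2 x distance-transform maximum) is >= min_width_px
filter_components_by_width <- function(bin, min_width_px) {
  if (!any(bin)) return(bin)
  lab <- EBImage::bwlabel(bin * 1)
  dt <- as.matrix(EBImage::distmap(bin * 1))
  width2 <- tapply(dt[bin], lab[bin], max) * 2
  keep_ids <- as.integer(names(width2)[width2 >= min_width_px])
  matrix(as.vector(lab) %in% keep_ids, nrow(bin), ncol(bin))
}
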