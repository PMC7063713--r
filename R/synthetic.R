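# Seeded generators for every input the pipeline consumes: layered
# B-scan phantoms with known boundary curves, en face angiogram phantoms
# with known vessel masks and capillary fractions, and three-group eye
# cohorts drawn from the published summary statistics. Every generator
# returns machine-readable ground truth beside the data.

#' Default layer intensity profile of the B-scan phantom
#'
#' Mean intensities (0--255) of, in depth order: vitreous, NFL, GCL+IPL,
#' INL, OPL, ONL, inner segments, outer segments, RPE, and below-RPE.
#' Chosen so each of the nine interfaces is, within its tracing band and
#' polarity, the strongest edge available to [segmentation_schedule()].
#'
#' @return Numeric vector of length 10.
#' @export
phantom_layer_intensities <- function() {
  c(vitreous = 10, NFL = 200, GCLIPL = 110, INL = 60, OPL = 130,
    ONL = 30, IS = 80, OS = 140, RPE = 230, below = 20)
}

#' Layered B-scan phantom with known boundaries
#'
#' Renders eight retinal layers between nine boundary curves, applies
#' Gaussian blur and multiplicative speckle, and returns the true
#' boundary positions beside the image.
#'
#' @param width,depth Raster size in px (cols, rows).
#' @param base_rows Row position of the nine boundaries at the left edge
#'   (strictly increasing).
#' @param shape `"flat"`, `"sine"` (common sinusoidal undulation) or
#'   `"pit"` (foveal-pit-like convergence of the inner boundaries at the
#'   scan center).
#' @param amplitude Shape amplitude in px.
#' @param period Sine period in px.
#' @param intensities Length-10 layer intensity vector; see
#'   [phantom_layer_intensities()].
#' @param speckle Multiplicative speckle SD (0 = none).
#' @param blur_sigma Gaussian blur SD in px (0 = none).
#' @param axial_scale,lateral_scale um/px metadata for the [bscan()].
#' @param meridian_angle,eye_axial_length Metadata for the [bscan()].
#' @param seed Integer seed (noise reproducibility).
#' @return List: `bscan` (a [bscan()]) and `truth` (9 x width integer
#'   matrix of true boundary rows).
#' @export
make_bscan_phantom <- function(width = 256, depth = 320,
                               base_rows = c(60, 78, 108, 130, 152, 180,
                                             200, 218, 240),
                               shape = c("flat", "sine", "pit"),
                               amplitude = 5, period = 120,
                               intensities = phantom_layer_intensities(),
                               speckle = 0, blur_sigma = 0,
                               axial_scale = 3, lateral_scale = 12,
                               meridian_angle = 0,
                               eye_axial_length = 23.95, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(length(base_rows) == 9, all(diff(base_rows) >= 0),
            length(intensities) == 10)
  set.seed(seed)
  x <- seq_len(width)
  B <- matrix(rep(base_rows, each = width), nrow = 9, byrow = TRUE)
  if (shape == "sine") {
    off <- amplitude * sin(2 * pi * x / period)
    B <- B + matrix(rep(off, 9), nrow = 9, byrow = TRUE)
  } else if (shape == "pit") {
    # inner boundaries dip toward the outer retina at the center
    bump <- exp(-((x - (width + 1) / 2) / (width / 8))^2)
    wts <- c(1, 0.8, 0.5, 0.25, 0.1, 0, 0, 0, 0)
    B <- B + amplitude * outer(wts, bump)
    for (b in 2:9) B[b, ] <- pmax(B[b, ], B[b - 1, ])
  }
  B <- round(B)
  storage.mode(B) <- "integer"
  if (max(B) > depth - 2 || min(B) < 2) {
    stop("boundaries exceed the image depth", call. = FALSE)
  }
  img <- matrix(intensities[1], depth, width)
  for (lay in 1:9) {
    upper <- B[lay, ]
    lower <- if (lay < 9) B[lay + 1, ] - 1 else rep(depth, width)
    lower <- if (lay < 9) pmax(lower, upper) else lower
    for (j in x) {
      if (lay < 9) {
        if (B[lay + 1, j] > B[lay, j]) {
          img[B[lay, j]:(B[lay + 1, j] - 1), j] <- intensities[lay + 1]
        }
      } else {
        img[B[9, j]:depth, j] <- intensities[10]
      }
    }
  }
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  if (speckle > 0) {
    img <- img * matrix(pmax(1 + rnorm(length(img), 0, speckle), 0),
                        depth, width)
  }
  list(
    bscan = bscan(img, axial_scale, lateral_scale, meridian_angle,
                  eye_axial_length),
    truth = B
  )
}

# stamp filled disks of the given radius at (row, col) sample points
.stamp_disks <- function(mask, rows, cols, radius) {
  n <- nrow(mask); m <- ncol(mask)
  rr <- ceiling(radius)
  offs <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    r <- round(rows) + offs$dr[k]
    c <- round(cols) + offs$dc[k]
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

#' En face angiogram phantom with known vessel truth
#'
#' Draws a zero-flow foveal avascular zone, a few wide high-intensity
#' vessels routed around it, and a capillary mesh (thresholded smoothed
#' random field) whose realized TAZ area fraction hits the target
#' exactly; adds background noise. Realized per-region capillary
#' fractions, the FAZ/vessel masks, and the FAZ area are returned as
#' truth.
#'
#' @param size Native raster edge in px (default 304).
#' @param field_of_view_mm Field in mm (default 3).
#' @param faz_shape `"disk"`, `"ellipse"` or `"irregular"`.
#' @param faz_diameter_mm FAZ diameter (mm); for an ellipse, the two axes
#'   are `faz_diameter_mm * c(1, faz_axis_ratio)`.
#' @param faz_axis_ratio Minor/major axis ratio for `"ellipse"`.
#' @param n_large_vessels Number of wide vessels.
#' @param vessel_width_um Width range (min, max) of large vessels in um.
#' @param capillary_fraction Target capillary area fraction of the TAZ
#'   (0--0.95).
#' @param mesh_sigma_px Smoothing SD of the mesh random field (controls
#'   capillary calibre).
#' @param intensity Named vector: `bg_mean`, `bg_sd`, `cap`, `cap_sd`,
#'   `large`, `large_sd` (0--255 scale).
#' @param layer,ssi,eye_id,laterality Angiogram metadata.
#' @param seed Integer seed.
#' @return List: `angiogram` (an [angiogram()]) and `truth` (list with
#'   `faz_mask`, `faz_area_mm2`, `large_mask`, `capillary_mask`, and a
#'   `region_fractions` tibble).
#' @export
make_angiogram_phantom <- function(size = 304, field_of_view_mm = 3,
                                   faz_shape = c("disk", "ellipse",
                                                 "irregular"),
                                   faz_diameter_mm = 0.60,
                                   faz_axis_ratio = 0.7,
                                   n_large_vessels = 4,
                                   vessel_width_um = c(32, 48),
                                   capillary_fraction = 0.637,
                                   mesh_sigma_px = 2.2,
                                   intensity = c(bg_mean = 25, bg_sd = 12,
                                                 cap = 100, cap_sd = 10,
                                                 large = 250, large_sd = 8),
                                   layer = "SRCL", ssi = 70,
                                   eye_id = "phantom",
                                   laterality = "OD", seed = 1) {
  faz_shape <- match.arg(faz_shape)
  stopifnot(capillary_fraction > 0, capillary_fraction <= 0.95)
  set.seed(seed)
  mmpp <- field_of_view_mm / size
  grid <- fovea_grid(size, size, mmpp, laterality = laterality)
  ctr <- c(grid$center_row, grid$center_col) + 1
  rr <- row(matrix(0, size, size)) - ctr[1]
  cc <- col(matrix(0, size, size)) - ctr[2]
  rad_px <- sqrt(rr^2 + cc^2)
  theta <- atan2(cc, -rr)

  r0 <- faz_diameter_mm / 2 / mmpp
  faz <- switch(faz_shape,
    disk = rad_px < r0,
    ellipse = sqrt((rr / (r0 * faz_axis_ratio))^2 + (cc / r0)^2) < 1,
    irregular = rad_px < r0 * (1 + 0.15 * sin(3 * theta + runif(1, 0, 2 * pi)))
  )

  # wide vessels: perturbed chords offset from the center so they avoid
  # the FAZ; widths drawn uniformly from the configured range
  large <- matrix(FALSE, size, size)
  for (v in seq_len(n_large_vessels)) {
    ang <- runif(1, 0, pi)
    off_mm <- sample(c(-1, 1), 1) * runif(1, 0.55, 1.35)
    off <- off_mm / mmpp
    w_px <- runif(1, vessel_width_um[1], vessel_width_um[2]) / (mmpp * 1000)
    t <- seq(-0.75 * size, 0.75 * size, by = 0.5)
    wig <- 6 * sin(2 * pi * t / (size / runif(1, 1.5, 2.5)) + runif(1, 0, 6))
    rows <- ctr[1] + off * -cos(ang) + t * sin(ang) + wig * -cos(ang)
    cols <- ctr[2] + off * sin(ang) + t * cos(ang) + wig * sin(ang)
    keep <- rows >= 1 & rows <= size & cols >= 1 & cols <= size
    large <- .stamp_disks(large, rows[keep], cols[keep], w_px / 2)
  }
  large <- large & !faz

  # capillary mesh: threshold of a band-pass noise field (difference of
  # Gaussians, so the mesh is locally homogeneous with no low-frequency
  # density patchiness), level set so the realized TAZ fraction equals
  # the target
  z <- matrix(rnorm(size^2), size, size)
  field <- gaussian_blur(z, mesh_sigma_px) -
    gaussian_blur(z, 4 * mesh_sigma_px)
  taz <- make_annulus_mask(grid, region_diameters_mm[["C"]],
                           region_diameters_mm[["TAZ"]])$pixels
  eligible <- !faz & !large
  need <- round(capillary_fraction * sum(taz))
  elig_taz <- eligible & taz
  if (need > 0.95 * sum(elig_taz)) {
    stop("target capillary fraction ", capillary_fraction,
         " unreachable given large-vessel coverage", call. = FALSE)
  }
  thr <- sort(field[elig_taz], decreasing = TRUE)[need]
  cap <- eligible & field >= thr

  img <- matrix(pmax(rnorm(size^2, intensity["bg_mean"],
                           intensity["bg_sd"]), 0), size, size)
  img[cap] <- rnorm(sum(cap), intensity["cap"], intensity["cap_sd"])
  img[large] <- rnorm(sum(large), intensity["large"],
                      intensity["large_sd"])
  img <- pmin(pmax(img, 0), 255)

  masks <- make_standard_masks(grid)
  regions <- c("TAZ", paste0("C", 1:6), "S", "T", "I", "N")
  fr <- tibble::tibble(
    region = regions,
    true_fraction = vapply(regions, function(rg)
      sum(cap & masks[[rg]]$pixels) / sum(masks[[rg]]$pixels), numeric(1))
  )
  list(
    angiogram = angiogram(img, layer = layer,
                          field_of_view_mm = field_of_view_mm,
                          signal_strength_index = ssi,
                          eye_id = eye_id, laterality = laterality),
    truth = list(faz_mask = faz, faz_area_mm2 = sum(faz) * mmpp^2,
                 large_mask = large, capillary_mask = cap,
                 region_fractions = fr)
  )
}

#' Cohort generator specification
#'
#' @param eyes_per_group Eyes in control / nonDON / DON (default
#'   38/36/38, the published cohort sizes).
#' @param bilateral_fraction Fraction of patients contributing both eyes
#'   (default 0.65; the published cohort has ~68% bilateral TAO
#'   patients).
#' @param rho_eye Within-patient inter-eye correlation of each measure
#'   (default 0.6; not reported by the study, a free parameter).
#' @param rho_xy Cross-measure correlation between `GCC_TAZ` and
#'   `SRCL_TAZ` (default 0.312, the reported pooled-TAO value).
#' @param stats Long reference table of per-measure group means/SDs
#'   (default [reference_stats()]).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(eyes_per_group = c(control = 38, nonDON = 36,
                                           DON = 38),
                        bilateral_fraction = 0.65,
                        rho_eye = 0.6, rho_xy = 0.312,
                        stats = reference_stats()) {
  stopifnot(all(eyes_per_group >= 2),
            bilateral_fraction >= 0, bilateral_fraction <= 1,
            rho_eye > -1, rho_eye < 1, rho_xy > -1, rho_xy < 1,
            all(stats$control_sd > 0))
  structure(list(eyes_per_group = eyes_per_group,
                 bilateral_fraction = bilateral_fraction,
                 rho_eye = rho_eye, rho_xy = rho_xy, stats = stats),
            class = "cohort_spec")
}

# split a per-group eye count into bilateral/unilateral patients
.patient_plan <- function(n_eyes, bilateral_fraction) {
  n_pat <- max(1, round(n_eyes / (1 + bilateral_fraction)))
  n_bi <- n_eyes - n_pat
  if (n_bi < 0) { n_pat <- n_eyes; n_bi <- 0 }
  if (n_bi > n_pat) { n_bi <- n_pat; n_pat <- n_eyes - n_bi }
  c(patients = n_pat, bilateral = n_bi)
}

#' Simulate a three-group eye cohort
#'
#' One row per eye. Each measure is drawn from its group-specific normal
#' with a shared within-patient latent component inducing inter-eye
#' correlation `rho_eye`; the designated pair (`GCC_TAZ`, `SRCL_TAZ`)
#' shares correlated standard-normal drivers so their total correlation
#' is `rho_xy`. Thickness and density values are truncated at 0.
#' Covariates (age, sex, axial length, IOP, BCVA, MD, CAS) are drawn
#' from the published demographic table.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble: `patient_id`, `eye`, `group`, one column per measure
#'   (`<layer>_<region>`), and covariate columns.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  st <- spec$stats
  measures <- paste(st$layer, st$region, sep = "_")
  M <- length(measures)
  pair <- c("GCC_TAZ", "SRCL_TAZ")
  i1 <- match(pair[1], measures); i2 <- match(pair[2], measures)
  rho_e <- spec$rho_eye; rho_xy <- spec$rho_xy
  cov_ref <- reference_stats("covariates")
  # correlate the designated pair in a standard-normal driver matrix
  correlate_pair <- function(Z) {
    if (!is.na(i1) && !is.na(i2)) {
      Z[, i2] <- rho_xy * Z[, i1] + sqrt(1 - rho_xy^2) * Z[, i2]
    }
    Z
  }
  groups <- purrr::map(names(spec$eyes_per_group), function(g) {
    plan <- .patient_plan(spec$eyes_per_group[[g]],
                          spec$bilateral_fraction)
    n_pat <- plan[["patients"]]; n_bi <- plan[["bilateral"]]
    mcol <- paste0(g, "_mean"); scol <- paste0(g, "_sd")
    mu <- st[[mcol]]; sg <- st[[scol]]
    n_per_pat <- ifelse(seq_len(n_pat) <= n_bi, 2L, 1L)
    pidx <- rep(seq_len(n_pat), n_per_pat)
    n_eye <- length(pidx)
    eye <- unlist(lapply(n_per_pat, function(k)
      if (k == 2) c("OD", "OS") else sample(c("OD", "OS"), 1)))
    Zp <- correlate_pair(matrix(rnorm(n_pat * M), n_pat, M))
    Ze <- correlate_pair(matrix(rnorm(n_eye * M), n_eye, M))
    Z <- sqrt(rho_e) * Zp[pidx, , drop = FALSE] + sqrt(1 - rho_e) * Ze
    vals <- pmax(sweep(sweep(Z, 2, sg, "*"), 2, mu, "+"), 0)
    colnames(vals) <- measures
    cov_par <- function(nm, n) {
      m <- cov_ref[[mcol]][cov_ref$covariate == nm]
      s <- cov_ref[[scol]][cov_ref$covariate == nm]
      if (is.na(m)) rep(NA_real_, n) else rnorm(n, m, s)
    }
    age_p <- cov_par("age", n_pat)
    cas_p <- pmax(cov_par("CAS", n_pat), 0)
    sex_p <- sample(c("M", "F"), n_pat, replace = TRUE)
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("%s_%02d", g, pidx),
                     eye = eye, group = g),
      tibble::as_tibble(vals),
      tibble::tibble(age = age_p[pidx], sex = sex_p[pidx],
                     axial_length = cov_par("axial_length", n_eye),
                     IOP = cov_par("IOP", n_eye),
                     BCVA = cov_par("BCVA", n_eye),
                     MD = cov_par("MD", n_eye),
                     CAS = cas_p[pidx]))
  })
  out <- dplyr::bind_rows(groups)
  out$group <- factor(out$group, levels = names(spec$eyes_per_group))
  out
}
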