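# Orchestration: per-eye quantification (B-scans -> regional
# thicknesses; angiograms -> regional RCDs) assembled into one eye
# record, and cohort-level reporting. Configuration is a plain named
# list serializable to/from YAML; cohort tools never read images.

#' Default pipeline configuration
#'
#' @return Nested named list with `geometry`, `segmentation`, `angio` and
#'   `stats` sections; round-trips losslessly through YAML.
#' @export
default_config <- function() {
  list(
    geometry = list(
      diameters_mm = as.list(region_diameters_mm),
      temporal_side = "left",
      map_size_px = 304,
      map_fov_mm = 3
    ),
    segmentation = list(
      max_step = 2,
      smooth_sigma = 1,
      reference_axial_length = 23.95
    ),
    angio = as.list(angio_defaults()),
    stats = list(alpha_general = 0.05, alpha_family = 0.01, seed = 1)
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config()`: the configuration list; `write_config()`:
#'   the path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  # order-stable serialization -> hex of a simple rolling hash
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Quantify regional layer thicknesses from radial B-scans
#'
#' Segments each meridional scan, converts boundary pairs to thickness
#' profiles (with axial-length magnification correction of the lateral
#' scale), interpolates each layer onto the fovea-centered map, and
#' averages over the C, TAZ and sector masks.
#'
#' @param bscans List of [bscan()] objects on evenly spaced meridians.
#' @param config Pipeline configuration ([default_config()]).
#' @param laterality `"OD"` or `"OS"` for sector orientation.
#' @return Tibble: layer, region, mean_um, n_pixels.
#' @export
quantify_thickness <- function(bscans, config = default_config(),
                               laterality = "OD") {
  stopifnot(length(bscans) >= 1)
  seg <- config$segmentation
  bsets <- lapply(bscans, segment_boundaries,
                  max_step = seg$max_step, smooth_sigma = seg$smooth_sigma)
  angles <- vapply(bscans, function(b) b$meridian_angle, numeric(1))
  ord <- order(angles %% 180)
  bsets <- bsets[ord]; bscans <- bscans[ord]
  angles <- (angles %% 180)[ord]
  mag <- magnification_correction(bscans[[1]]$eye_axial_length,
                                  seg$reference_axial_length)
  lat_um <- bscans[[1]]$lateral_scale * mag
  n_px <- config$geometry$map_size_px
  grid <- fovea_grid(n_px, n_px, config$geometry$map_fov_mm / n_px,
                     laterality = laterality)
  masks <- c(
    list(C = make_annulus_mask(grid, 0, region_diameters_mm[["C"]], "C"),
         TAZ = make_annulus_mask(grid, region_diameters_mm[["C"]],
                                 region_diameters_mm[["TAZ"]], "TAZ")),
    make_sector_masks(grid, region_diameters_mm[["C"]],
                      region_diameters_mm[["TAZ"]],
                      temporal_side = config$geometry$temporal_side))
  pairs <- layer_boundary_pairs()
  purrr::map_dfr(names(pairs), function(layer) {
    prof <- t(vapply(bsets, function(bs)
      layer_thickness(bs, pairs[[layer]][1], pairs[[layer]][2]),
      numeric(ncol(bsets[[1]]$boundaries))))
    map <- radial_to_map(prof, angles, grid, lat_um, layer_name = layer)
    regional_mean_thickness(map, masks)
  })
}

#' Quantify one eye: thicknesses plus capillary densities
#'
#' Runs [quantify_thickness()] on the structural scans and
#' [rcd_profile()] on each angiogram (SRCL/DRCL). Angiograms failing the
#' SSI gate contribute NA densities; in strict mode any stage failure is
#' an error.
#'
#' @param bscans List of [bscan()] objects (may be empty).
#' @param angiograms List of [angiogram()] objects (may be empty).
#' @param config Pipeline configuration.
#' @param eye_id,laterality Identifiers.
#' @param strict Error on any stage failure instead of recording NA.
#' @return One-row wide tibble: identifiers, `<layer>_<region>` measure
#'   columns, and a `complete` flag.
#' @export
run_eye <- function(bscans = list(), angiograms = list(),
                    config = default_config(),
                    eye_id = "eye", laterality = "OD", strict = FALSE) {
  out <- tibble::tibble(eye_id = eye_id, laterality = laterality)
  complete <- TRUE
  layer_code <- c(NFL = "NFL", `GCL+IPL` = "GCLIPL", GCC = "GCC",
                  `INL+ORL` = "INLORL", TOTAL = "TOTAL")
  if (length(bscans) > 0) {
    th <- tryCatch(
      quantify_thickness(bscans, config, laterality),
      error = function(e) if (strict) stop(e) else NULL)
    if (is.null(th)) complete <- FALSE
    else {
      wide <- th |>
        dplyr::mutate(col = paste0(layer_code[.data$layer], "_",
                                   .data$region)) |>
        dplyr::select("col", "mean_um") |>
        tidyr::pivot_wider(names_from = "col", values_from = "mean_um")
      out <- dplyr::bind_cols(out, wide)
    }
  }
  for (ang in angiograms) {
    prof <- tryCatch(
      rcd_profile(ang, params = config$angio),
      error = function(e) if (strict && !grepl("quality gate",
                                               conditionMessage(e)))
        stop(e) else NULL)
    if (is.null(prof)) {
      complete <- FALSE
      cols <- paste0(ang$layer, "_", c("TAZ", paste0("C", 1:6),
                                       "S", "T", "I", "N"))
      out[cols] <- NA_real_
    } else {
      wide <- prof |>
        dplyr::mutate(col = paste0(.data$layer, "_", .data$region)) |>
        dplyr::select("col", "rcd_percent") |>
        tidyr::pivot_wider(names_from = "col",
                           values_from = "rcd_percent")
      out <- dplyr::bind_cols(out, wide)
    }
  }
  out$complete <- complete
  out
}

#' Group-comparison table for a family of measures
#'
#' [group_compare()] applied to every measure column, emitting the
#' published table shape: per-group mean +/- SD and the three pairwise
#' p-values with the family significance rule.
#'
#' @param records Eye-record data frame (`patient_id`, `group`, measure
#'   columns).
#' @param measures Character vector of measure columns.
#' @param alpha Family significance level.
#' @return Tibble, one row per measure.
#' @export
compare_table <- function(records, measures, alpha = 0.01) {
  purrr::map_dfr(measures, function(m) {
    gc <- group_compare(records, m, alpha = alpha)
    s <- gc$summary
    fmt <- function(g) {
      i <- which(s$group == g)
      if (length(i) == 0) return(NA_character_)
      sprintf("%.1f ± %.1f", s$mean[i], s$sd[i])
    }
    pw <- gc$pairwise
    pget <- function(a, b) {
      i <- which(pw$group_a == a & pw$group_b == b |
                   pw$group_a == b & pw$group_b == a)
      if (length(i) == 0) NA_real_ else pw$p_value[i]
    }
    tibble::tibble(
      measure = m,
      control = fmt("control"), nonDON = fmt("nonDON"), DON = fmt("DON"),
      p_C_vs_N = pget("control", "nonDON"),
      p_C_vs_D = pget("control", "DON"),
      p_N_vs_D = pget("nonDON", "DON"),
      alpha = alpha)
  })
}

#' Cohort report bundle
#'
#' From a wide eye-record table, emits the thickness-comparison table,
#' the RCD-comparison table, the structure/perfusion correlation table
#' (GCC thickness vs SRCL RCD over the pooled TAO eyes), the single and
#' composite ROC table, and a run manifest (config hash, seed). With
#' `out_dir` set, each table is also written as CSV.
#'
#' @param records Wide eye-record tibble (as from [make_cohort()] or
#'   stacked [run_eye()] rows joined with group labels).
#' @param config Pipeline configuration.
#' @param out_dir Optional output directory for CSV files.
#' @return Named list of tibbles: `thickness`, `rcd`, `correlations`,
#'   `roc`, `manifest`.
#' @export
run_cohort <- function(records, config = default_config(),
                       out_dir = NULL) {
  if (length(unique(records$group)) < 2) {
    stop("cohort must contain at least two groups", call. = FALSE)
  }
  need <- c("patient_id", "group")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  alpha <- config$stats$alpha_family
  th_measures <- intersect(
    paste(rep(c("NFL", "GCLIPL", "GCC", "INLORL", "TOTAL"), each = 6),
          c("C", "TAZ", "S", "T", "I", "N"), sep = "_"),
    names(records))
  rcd_measures <- intersect(
    paste(rep(c("SRCL", "DRCL"), each = 11),
          c("TAZ", paste0("C", 1:6), "S", "T", "I", "N"), sep = "_"),
    names(records))
  thickness <- compare_table(records, th_measures, alpha = alpha)
  rcd_tbl <- compare_table(records, rcd_measures, alpha = alpha)
  tao <- records$group %in% c("nonDON", "DON")
  cors <- purrr::map_dfr(c("TAZ", "T", "I", "N", "S"), function(rg) {
    x <- paste0("GCC_", rg); y <- paste0("SRCL_", rg)
    if (!all(c(x, y) %in% names(records))) return(tibble::tibble())
    pearson(records, x, y, subset = tao)
  })
  roc <- roc_report(records)
  manifest <- tibble::tibble(
    config_hash = config_hash(config),
    seed = config$stats$seed,
    n_eyes = nrow(records),
    n_patients = length(unique(records$patient_id)),
    package_version = as.character(utils::packageVersion("maculaquant")))
  bundle <- list(thickness = thickness, rcd = rcd_tbl,
                 correlations = cors, roc = roc, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle)) {
      write.csv(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  bundle
}

# ---- raster I/O -----------------------------------------------------------

#' Read / write an angiogram as 8-bit grayscale PNG plus JSON sidecar
#'
#' The sidecar `<path>.json` carries layer, field of view, SSI, eye id
#' and laterality. Intensities are stored 0--255.
#'
#' @param angio An [angiogram()].
#' @param path PNG path.
#' @return `write_angiogram()`: the path, invisibly;
#'   `read_angiogram()`: an [angiogram()].
#' @export
write_angiogram <- function(angio, path) {
  png::writePNG(pmin(pmax(angio$intensity / 255, 0), 1), path)
  jsonlite::write_json(
    list(layer = angio$layer, field_of_view_mm = angio$field_of_view_mm,
         signal_strength_index = angio$signal_strength_index,
         eye_id = angio$eye_id, laterality = angio$laterality),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_angiogram
#' @export
read_angiogram <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  angiogram(img * 255, layer = meta$layer,
            field_of_view_mm = meta$field_of_view_mm,
            signal_strength_index = meta$signal_strength_index %||% NA_real_,
            eye_id = meta$eye_id %||% NA_character_,
            laterality = meta$laterality %||% NA_character_)
}

#' Read / write a B-scan as 8-bit grayscale PNG plus JSON sidecar
#'
#' @param scan A [bscan()].
#' @param path PNG path.
#' @return `write_bscan()`: the path, invisibly; `read_bscan()`: a
#'   [bscan()].
#' @export
write_bscan <- function(scan, path) {
  png::writePNG(pmin(pmax(scan$intensity / 255, 0), 1), path)
  jsonlite::write_json(
    list(axial_scale = scan$axial_scale,
         lateral_scale = scan$lateral_scale,
         meridian_angle = scan$meridian_angle,
         eye_axial_length = scan$eye_axial_length),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bscan(img * 255, axial_scale = meta$axial_scale,
        lateral_scale = meta$lateral_scale,
        meridian_angle = meta$meridian_angle,
        eye_axial_length = meta$eye_axial_length)
}

#' Write a thickness map as 32-bit TIFF
#'
#' Values are stored in millimetres (um / 1000) so they fit the [0, 1]
#' sample range of the format; missing pixels are stored as 0.
#'
#' @param map A `thickness_map`.
#' @param path TIFF path.
#' @export
write_thickness_map <- function(map, path) {
  v <- map$values / 1000
  v[is.na(v) | v < 0] <- 0
  tiff::writeTIFF(pmin(v, 1), path, bits.per.sample = 32L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
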