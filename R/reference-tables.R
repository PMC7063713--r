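# Published group summary statistics (mean, SD per group) for the
# regional thickness and capillary-density measures, used as the default
# parameters of the synthetic cohort generator and as inputs to the
# closed-form ROC cross-checks. Layer codes: NFL, GCLIPL (GCL+IPL), GCC,
# INLORL (INL+outer retina), TOTAL (full retina), SRCL/DRCL (RCD %).

.thickness_reference <- function() {
  tibble::tribble(
    ~layer, ~region, ~control_mean, ~control_sd, ~nonDON_mean, ~nonDON_sd, ~DON_mean, ~DON_sd,
    "NFL", "C",     6.9,  1.3,  6.2,  1.7,  6.9,  1.3,
    "NFL", "TAZ",  19.9,  3.2, 17.7,  2.1, 17.4,  1.3,
    "NFL", "S",    21.4,  3.6, 19.1,  3.3, 18.0,  1.9,
    "NFL", "T",    17.0,  2.7, 15.5,  1.9, 15.3,  1.9,
    "NFL", "I",    22.2,  3.6, 19.1,  3.3, 18.0,  1.9,
    "NFL", "N",    19.3,  4.6, 16.3,  2.2, 16.5,  1.8,
    "GCLIPL", "C",   14.6,  4.2, 12.0,  4.1, 12.0,  3.4,
    "GCLIPL", "TAZ", 75.4,  8.3, 69.6, 10.2, 67.1, 13.1,
    "GCLIPL", "S",   79.5,  9.6, 71.6, 11.0, 69.2, 14.2,
    "GCLIPL", "T",   72.0, 13.4, 65.1, 10.4, 62.7, 12.8,
    "GCLIPL", "I",   79.5,  9.6, 71.6, 11.0, 69.2, 14.2,
    "GCLIPL", "N",   74.9,  9.8, 66.8, 10.6, 64.9, 13.2,
    "GCC", "C",    21.5,  5.0, 18.2,  5.0, 18.9,  3.7,
    "GCC", "TAZ",  95.2, 10.3, 87.3, 11.8, 84.5, 13.4,
    "GCC", "S",   100.8, 12.0, 90.6, 13.1, 87.2, 15.0,
    "GCC", "T",    88.9, 14.5, 80.6, 11.8, 78.0, 11.9,
    "GCC", "I",   101.6, 13.1, 92.7, 12.5, 90.1, 14.0,
    "GCC", "N",    94.2, 13.2, 83.1, 12.2, 81.4, 13.2,
    "INLORL", "C",   202.2, 41.2, 202.9,  9.6, 206.3, 26.4,
    "INLORL", "TAZ", 219.3,  9.4, 218.4,  7.1, 221.4,  9.4,
    "INLORL", "S",   219.6,  9.9, 219.3,  7.5, 221.6,  9.2,
    "INLORL", "T",   221.8, 10.5, 220.2,  8.2, 224.0, 10.2,
    "INLORL", "I",   216.5,  8.0, 216.6,  7.2, 219.9,  9.3,
    "INLORL", "N",   218.6,  9.6, 217.1,  6.8, 220.5, 10.0,
    "TOTAL", "C",   213.3, 51.3, 214.7, 14.9, 215.8, 36.9,
    "TOTAL", "TAZ", 314.1, 17.5, 305.4, 15.8, 305.7, 12.8,
    "TOTAL", "S",   320.2, 19.5, 309.7, 17.1, 308.5, 14.8,
    "TOTAL", "T",   315.9, 21.8, 302.9, 17.5, 305.0, 14.9,
    "TOTAL", "I",   318.1, 19.1, 309.2, 15.4, 309.6, 12.9,
    "TOTAL", "N",   307.0, 21.5, 297.1, 15.0, 298.0, 11.5
  )
}

.rcd_reference <- function() {
  tibble::tribble(
    ~layer, ~region, ~control_mean, ~control_sd, ~nonDON_mean, ~nonDON_sd, ~DON_mean, ~DON_sd,
    "SRCL", "TAZ", 63.7,  3.3, 60.0,  3.5, 59.8,  4.5,
    "SRCL", "C1",  57.6, 12.9, 48.5, 14.6, 51.1, 11.6,
    "SRCL", "C2",  63.0,  5.6, 60.6,  5.8, 60.8,  5.2,
    "SRCL", "C3",  64.0,  4.5, 61.0,  4.3, 61.2,  5.5,
    "SRCL", "C4",  64.4,  3.7, 61.4,  4.0, 60.3,  5.3,
    "SRCL", "C5",  64.8,  3.1, 60.8,  3.8, 60.9,  5.0,
    "SRCL", "C6",  64.2,  2.9, 61.4,  3.6, 60.0,  4.4,
    "SRCL", "S",   63.4,  3.9, 60.3,  4.3, 60.0,  5.3,
    "SRCL", "T",   64.0,  3.5, 61.2,  4.2, 60.3,  5.0,
    "SRCL", "I",   63.7,  3.6, 59.7,  4.0, 59.5,  5.6,
    "SRCL", "N",   63.6,  4.3, 59.0,  4.0, 59.5,  4.5,
    "DRCL", "TAZ", 73.9,  4.8, 70.2,  4.4, 66.4,  7.7,
    "DRCL", "C1",  40.6, 18.8, 34.0, 16.2, 29.7, 15.3,
    "DRCL", "C2",  71.6,  8.5, 66.7,  8.4, 61.3, 12.4,
    "DRCL", "C3",  78.3,  4.1, 75.2,  4.3, 71.9,  7.5,
    "DRCL", "C4",  78.4,  4.0, 75.9,  3.6, 72.3,  7.4,
    "DRCL", "C5",  77.8,  3.6, 74.4,  3.9, 71.3,  7.7,
    "DRCL", "C6",  76.5,  4.2, 72.9,  4.1, 68.9,  8.1,
    "DRCL", "S",   75.0,  4.6, 71.2,  4.1, 68.0,  8.1,
    "DRCL", "T",   73.4,  4.7, 69.4,  5.1, 65.1,  9.2,
    "DRCL", "I",   75.0,  4.9, 71.5,  4.9, 67.7,  7.0,
    "DRCL", "N",   72.4,  5.7, 68.8,  4.6, 64.8,  7.9
  )
}

.covariate_reference <- function() {
  tibble::tribble(
    ~covariate, ~level, ~control_mean, ~control_sd, ~nonDON_mean, ~nonDON_sd, ~DON_mean, ~DON_sd,
    "age",  "patient", 45.2, 10.8,  41.9, 11.7,  47.6,  6.5,
    "axial_length", "eye", 23.5, 0.9, 23.3, 1.0, 23.3, 0.8,
    "IOP",  "eye",     14.4,  2.3,  16.1,  3.2,  19.0,  6.9,
    "BCVA", "eye",      0.00, 0.01,  0.00, 0.01,  0.15, 0.37,
    "MD",   "eye",        NA,   NA, -0.29, 0.54, -6.79, 3.91,
    "CAS",  "patient",    NA,   NA,  1.08, 1.18,  1.73, 1.12
  )
}

#' Reference group summary statistics
#'
#' Published per-region group means and SDs of the regional layer
#' thicknesses (um) and capillary densities (%), in long form. These are
#' the default parameters of [make_cohort()] and the inputs of the
#' binormal ROC cross-checks.
#'
#' @param what `"thickness"`, `"rcd"`, `"covariates"`, or `"all"` (both
#'   measure tables bound together).
#' @return Tibble: layer, region, and mean/SD columns per group.
#' @export
reference_stats <- function(what = c("all", "thickness", "rcd",
                                     "covariates")) {
  what <- match.arg(what)
  switch(what,
    thickness = .thickness_reference(),
    rcd = .rcd_reference(),
    covariates = .covariate_reference(),
    all = dplyr::bind_rows(.thickness_reference(), .rcd_reference())
  )
}
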