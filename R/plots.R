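# ggplot2 views of the result objects.

raster_df <- function(m) {
  tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    value = as.vector(m))
}

#' Plot a thickness map
#'
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @return A ggplot raster of the map in micrometres (row 1 at the top).
#' @method autoplot thickness_map
#' @export
autoplot.thickness_map <- function(object, ...) {
  df <- raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "µm", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$layer_name, "thickness"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a region mask
#'
#' @param object A `region_mask`.
#' @param ... Unused.
#' @return A ggplot raster of the mask.
#' @method autoplot region_mask
#' @export
autoplot.region_mask <- function(object, ...) {
  df <- raster_df(object$pixels * 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#2166ac")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("region", object$name), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a regional capillary-density profile
#'
#' @param object The tibble returned by [rcd_profile()].
#' @param ... Unused.
#' @return A ggplot bar chart of RCD by region.
#' @method autoplot rcd_profile
#' @export
autoplot.rcd_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region, levels = c("TAZ", paste0("C", 1:6),
                                            "S", "T", "I", "N"))
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$rcd_percent)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(title = paste("RCD,", df$layer[1]),
                  x = NULL, y = "RCD (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' ROC-style summary plot of an ROC report
#'
#' Dot plot of the AUCs in a [roc_report()] table, grouped by indicator
#' kind (single vs composite).
#'
#' @param roc_table Tibble from [roc_report()].
#' @return A ggplot.
#' @export
plot_roc_report <- function(roc_table) {
  ggplot2::ggplot(roc_table,
                  ggplot2::aes(.data$auc,
                               stats::reorder(.data$indicator, .data$auc),
                               colour = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "AUC", y = NULL, colour = NULL) +
    ggplot2::xlim(0.4, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
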