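# ggplot2 views of the result tables.

#' Plot an absorption spectrum
#'
#' @param object an `absorption_spectrum` from [absorption_spectrum()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.absorption_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$detuning, y = .data$mu_a)) +
    ggplot2::geom_line(colour = "#2c5aa0") +
    ggplot2::labs(x = expression(paste("detuning (", cm^-1, ")")),
                  y = expression(paste(mu[a], " (", cm^-1, ")"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-configuration pathlength summary plot
#'
#' Mean +/- SD calculated pathlength per source-detector configuration,
#' faceted by illumination mode — the layout used to compare transmittance
#' and remittance placements.
#'
#' @param summaries an [aggregate_replicates()] table; if the estimates
#'   carried design columns (`illumination`, `detector_position`), joins can
#'   be supplied via `design`.
#' @param design optional design/truth tibble with `config_id`,
#'   `illumination` and `detector_position`, used for ordering and faceting.
#' @return a ggplot object.
#' @export
plot_pathlength_summary <- function(summaries, design = NULL) {
  df <- summaries
  if (!is.null(design)) {
    df <- dplyr::left_join(
      df,
      dplyr::distinct(design[, c("config_id", "illumination",
                                 "detector_position")]),
      by = "config_id"
    )
  }
  if (!"illumination" %in% names(df)) df$illumination <- "all"
  if (!"detector_position" %in% names(df)) {
    df$detector_position <- seq_len(nrow(df))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$detector_position),
                                   y = 1000 * .data$mean_pathlength_m)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = 1000 * (.data$mean_pathlength_m - .data$sd_pathlength_m),
      ymax = 1000 * (.data$mean_pathlength_m + .data$sd_pathlength_m)),
      colour = "#2c5aa0", na.rm = TRUE) +
    ggplot2::facet_wrap(~illumination, scales = "free_x") +
    ggplot2::labs(x = "detector position", y = "pathlength (mm)") +
    ggplot2::theme_minimal()
}

#' Concentration box plot
#'
#' Box statistics of estimated O2 concentration per nominal concentration
#' group, with the nominal values as dotted reference lines and fence
#' outliers as points.
#'
#' @param boxes a [concentration_boxes()] table.
#' @return a ggplot object.
#' @export
plot_concentration_boxes <- function(boxes) {
  outliers <- tidyr::unnest(boxes[, c("group", "outlier_values")],
                            cols = "outlier_values")
  ggplot2::ggplot(boxes, ggplot2::aes(x = factor(100 * .data$group))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$whisker_low,
                                        ymax = 100 * .data$whisker_high),
                           width = 0.25) +
    ggplot2::geom_crossbar(ggplot2::aes(y = 100 * .data$median,
                                        ymin = 100 * .data$q1,
                                        ymax = 100 * .data$q3),
                           fill = "white", colour = "black", width = 0.5,
                           fatten = 0) +
    ggplot2::geom_crossbar(ggplot2::aes(y = 100 * .data$median,
                                        ymin = 100 * .data$median,
                                        ymax = 100 * .data$median),
                           colour = "red", width = 0.5) +
    ggplot2::geom_point(data = outliers,
                        ggplot2::aes(y = 100 * .data$outlier_values),
                        shape = 1) +
    ggplot2::geom_point(ggplot2::aes(y = 100 * .data$group), shape = 95,
                        size = 8, colour = "grey40") +
    ggplot2::labs(x = "nominal O2 concentration (%)",
                  y = "estimated O2 concentration (%)") +
    ggplot2::theme_minimal()
}
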