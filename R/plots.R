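#' Top-down view of a point cloud
#'
#' Plots the (x, y) footprint of a cloud coloured by height, per-point NDVI,
#' or approximate RGB colour — the quick visual check that a scan covers the
#' sector and that segmentation thresholds are sensible.
#'
#' @param cloud A point-cloud tibble.
#' @param colour `"height"`, `"ndvi"` or `"rgb"`.
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, colour = c("height", "ndvi", "rgb"), point_size = 0.3) {
  colour <- match.arg(colour)
  p <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
  if (colour == "height") {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$z), size = point_size) +
      ggplot2::scale_colour_viridis_c(name = "z [mm]")
  } else if (colour == "ndvi") {
    cloud$ndvi_pt <- ndvi(cloud$nir, cloud$red)
    p %+% cloud + ggplot2::geom_point(ggplot2::aes(colour = .data$ndvi_pt), size = point_size) +
      ggplot2::scale_colour_gradient2(name = "NDVI", low = "sienna",
                                      mid = "khaki", high = "darkgreen",
                                      midpoint = 0.3)
  } else {
    rgbcol <- grDevices::rgb(pmin(1, cloud$red / max(cloud$red, 1e-9)),
                             pmin(1, cloud$green / max(cloud$green, 1e-9)),
                             pmin(1, cloud$blue / max(cloud$blue, 1e-9)))
    p + ggplot2::geom_point(colour = rgbcol, size = point_size)
  }
}

#' @importFrom ggplot2 %+%
NULL

#' Classification accuracy over scan events
#'
#' Line plot of per-event classification accuracy for each target, with the
#' chance level of each target shown as a dashed line.
#'
#' @param accuracy A tibble from [accuracy_timeseries()] (rows for several
#'   targets can be bound together).
#' @param chance Optional named vector of chance levels per target; by
#'   default 1/2 for binary targets, 1/4 for treatment, 1/3 for region.
#' @return A ggplot object.
#' @export
plot_accuracy_timeseries <- function(accuracy, chance = NULL) {
  if (is.null(chance)) {
    chance <- c(region = 1 / 3, treatment = 1 / 4, mown = 1 / 2, fertilized = 1 / 2)
  }
  ch <- tibble::tibble(
    target = names(chance)[names(chance) %in% unique(accuracy$target)],
    level = chance[names(chance) %in% unique(accuracy$target)]
  )
  ggplot2::ggplot(accuracy, ggplot2::aes(
    x = .data$scan_event, y = .data$accuracy,
    colour = .data$target, group = .data$target
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = ch, ggplot2::aes(yintercept = .data$level,
                                                colour = .data$target),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "scan event", y = "classification accuracy") +
    ggplot2::theme_minimal()
}
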