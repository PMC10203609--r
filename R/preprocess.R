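#' Correct reflectance for distance attenuation
#'
#' Laser-return intensity falls off with the distance between the canopy and
#' the sensor. With an inverse-power attenuation model, a channel value `v`
#' recorded at distance `d = sensor_height - z` is restored to its value at
#' the reference distance by `v * (d / d_ref)^exponent`, then clamped to
#' `[0, 1]`. `exponent = 2` is the inverse-square default; `exponent = 0` is
#' the identity.
#'
#' @param cloud A point-cloud tibble.
#' @param config A [scan_config()]; supplies `sensor_height` and
#'   `attenuation_reference_distance`.
#' @param exponent Attenuation exponent (default 2).
#' @return The cloud with corrected channels.
#' @export
correct_distance_attenuation <- function(cloud, config = scan_config(), exponent = 2) {
  if (nrow(cloud) == 0) return(cloud)
  if (config$sensor_height <= max(cloud$z)) {
    stop("sensor_height (", config$sensor_height,
         " mm) must exceed the tallest point (z = ", max(cloud$z), " mm)",
         call. = FALSE)
  }
  d <- config$sensor_height - cloud$z
  f <- (d / config$attenuation_reference_distance)^exponent
  cloud[cloud_channels] <- lapply(cloud[cloud_channels], function(v) {
    pmin(1, pmax(0, v * f))
  })
  cloud
}

#' Calibrate point heights to the soil plane
#'
#' With `method = "fixed_zero"` the cloud is assumed already soil-referenced
#' (the scanner's reference barcodes define above-ground height) and z is
#' returned unchanged with a soil plane at 0. With `"lower_percentile"` the
#' soil plane is estimated as a low percentile of z (default the 1st) and all
#' z are shifted so that plane becomes 0.
#'
#' @param cloud A point-cloud tibble (non-empty).
#' @param method `"fixed_zero"` or `"lower_percentile"`.
#' @param percentile Percentile (in percent) of z used as the soil plane for
#'   `"lower_percentile"`.
#' @return The cloud, with the estimated plane height stored in attribute
#'   `soil_plane_z` (relative to the input z).
#' @export
calibrate_soil_plane <- function(cloud,
                                 method = c("fixed_zero", "lower_percentile"),
                                 percentile = 1) {
  method <- match.arg(method)
  if (nrow(cloud) == 0) stop("cannot calibrate an empty cloud", call. = FALSE)
  plane <- switch(method,
    fixed_zero = 0,
    lower_percentile = unname(stats::quantile(cloud$z, percentile / 100))
  )
  cloud$z <- cloud$z - plane
  attr(cloud, "soil_plane_z") <- plane
  cloud
}

#' Flag isolated points as noise
#'
#' Computes each point's mean 3D distance to its `k_neighbors` nearest
#' neighbours and flags points whose mean distance exceeds the global mean by
#' more than `sigma` standard deviations. Deterministic for a fixed input.
#'
#' @param cloud A point-cloud tibble.
#' @param k_neighbors Number of neighbours (>= 1).
#' @param sigma Flagging threshold in standard deviations.
#' @return The cloud with a logical `noise` column.
#' @export
remove_outliers <- function(cloud, k_neighbors = 8, sigma = 3) {
  stopifnot(k_neighbors >= 1)
  if (nrow(cloud) < k_neighbors + 1) {
    if (nrow(cloud) > 0) {
      warning("fewer than k_neighbors + 1 points; no outlier flags set", call. = FALSE)
    }
    cloud$noise <- rep(FALSE, nrow(cloud))
    return(cloud)
  }
  nn <- FNN::get.knn(as.matrix(cloud[, c("x", "y", "z")]), k = k_neighbors)
  mean_dist <- rowMeans(nn$nn.dist)
  cloud$noise <- mean_dist > mean(mean_dist) + sigma * stats::sd(mean_dist)
  cloud
}

#' Segment plant from soil points
#'
#' Labels each point `plant`, `soil` or `noise`. A point is labelled plant if
#' its per-point NDVI exceeds `ndvi_threshold` (bare soil typically sits at
#' NDVI 0.1-0.2, vegetation above) or if it lies above `min_height`; otherwise
#' soil. Points with an undefined NDVI (NIR + RED = 0) and points already
#' flagged by [remove_outliers()] are labelled noise, never silently treated
#' as index 0.
#'
#' @param cloud A point-cloud tibble, optionally carrying a `noise` column.
#' @param ndvi_threshold NDVI above which a point counts as vegetation
#'   (default 0.2).
#' @param min_height Height in mm above which a point counts as vegetation
#'   regardless of NDVI (default 20).
#' @return The cloud with a `label` factor column
#'   (`plant`/`soil`/`noise`).
#' @export
segment_plants <- function(cloud, ndvi_threshold = 0.2, min_height = 20) {
  nd <- ndvi(cloud$nir, cloud$red)
  label <- ifelse(is.na(nd), "noise",
    ifelse(nd > ndvi_threshold | cloud$z > min_height, "plant", "soil")
  )
  if ("noise" %in% colnames(cloud)) label[cloud$noise] <- "noise"
  cloud$label <- factor(label, levels = c("plant", "soil", "noise"))
  cloud
}

#' Count points per segmentation label
#'
#' @param seg A segmented cloud (from [segment_plants()]).
#' @return A tibble with one row per label and its count.
#' @export
segmentation_summary <- function(seg) {
  stopifnot("label" %in% colnames(seg))
  dplyr::count(seg, .data$label, name = "n", .drop = FALSE)
}

plant_points <- function(seg) {
  stopifnot("label" %in% colnames(seg))
  seg[seg$label == "plant", , drop = FALSE]
}
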