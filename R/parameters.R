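#' Canopy percentile statistics
#'
#' `top_fraction_mean()` averages the largest `ceiling(frac * n)` values,
#' `bottom_fraction_mean()` the smallest. At least one value is always
#' included for non-empty input.
#'
#' @param z Numeric vector.
#' @param frac Fraction in (0, 1].
#' @return The mean of the selected values, `NA` for empty input.
#' @keywords internal
top_fraction_mean <- function(z, frac) {
  n <- length(z)
  if (n == 0) return(NA_real_)
  k <- max(1L, ceiling(frac * n))
  mean(sort(z, decreasing = TRUE)[seq_len(k)])
}

#' @rdname top_fraction_mean
#' @keywords internal
bottom_fraction_mean <- function(z, frac) {
  n <- length(z)
  if (n == 0) return(NA_real_)
  k <- max(1L, ceiling(frac * n))
  mean(sort(z)[seq_len(k)])
}

#' Community canopy height
#'
#' Mean height of the top 10% of plant points: the range from soil to the
#' averaged top decile of the canopy. Returns 0 for an empty canopy.
#'
#' @param seg A segmented cloud.
#' @return Height in mm.
#' @export
compute_height <- function(seg) {
  z <- plant_points(seg)$z
  if (length(z) == 0) return(0)
  top_fraction_mean(z, 0.10)
}

#' Maximum canopy height
#'
#' The highest plant point of the community; 0 for an empty canopy.
#'
#' @param seg A segmented cloud.
#' @return Height in mm.
#' @export
compute_height_max <- function(seg) {
  z <- plant_points(seg)$z
  if (length(z) == 0) return(0)
  max(z)
}

#' Light penetration depth
#'
#' Vertical distance between the averaged top 10% and the averaged bottom 20%
#' of plant returns: how deep the laser reaches into the canopy. 0 for a
#' single-layer or empty canopy.
#'
#' @param seg A segmented cloud.
#' @return Depth in mm (>= 0).
#' @export
compute_light_penetration <- function(seg) {
  z <- plant_points(seg)$z
  if (length(z) == 0) return(0)
  max(0, top_fraction_mean(z, 0.10) - bottom_fraction_mean(z, 0.20))
}

#' 3D leaf area of a surface mesh
#'
#' Sum of triangle areas of the reconstructed canopy surface: the digital
#' leaf area corrected for leaf inclination. 0 for an empty or degenerate
#' mesh.
#'
#' @param mesh A `triangle_mesh` from [reconstruct_surface()].
#' @return Area in mm^2.
#' @export
compute_leaf_area <- function(mesh) {
  sum(mesh$area)
}

#' Projected (2D) leaf area
#'
#' The amount of the sector ground covered by leaves: the number of
#' `grid_resolution`-sized cells containing at least one plant point, times
#' the cell area.
#'
#' @param seg A segmented cloud.
#' @param config A [scan_config()]; supplies `grid_resolution`.
#' @return Area in mm^2.
#' @export
compute_projected_area <- function(seg, config = scan_config()) {
  pl <- plant_points(seg)
  if (nrow(pl) == 0) return(0)
  res <- config$grid_resolution
  cells <- paste(floor(pl$x / res), floor(pl$y / res))
  length(unique(cells)) * res^2
}

#' Leaf area index
#'
#' 3D leaf area per unit sector ground area.
#'
#' @param leaf_area 3D leaf area in mm^2.
#' @param config A [scan_config()].
#' @return Dimensionless LAI.
#' @export
compute_leaf_area_index <- function(leaf_area, config = scan_config()) {
  leaf_area / sector_area(config)
}

#' Community leaf angle
#'
#' Area-weighted mean angle of the leaf surfaces to the perpendicular:
#' 0 degrees is a vertical leaf, 90 degrees a horizontal one. Each triangle
#' contributes `90 - tilt`, where tilt is the angle between its normal and
#' the vertical axis, weighted by its area. `NA` (undefined, not 0) for an
#' empty mesh.
#'
#' @param mesh A `triangle_mesh`.
#' @return Angle in degrees in `[0, 90]`, or `NA`.
#' @export
compute_leaf_angle <- function(mesh) {
  if (length(mesh$area) == 0) return(NA_real_)
  tilt <- acos(pmin(1, pmax(-1, mesh$normal[, 3]))) * 180 / pi
  stats::weighted.mean(90 - tilt, mesh$area)
}

#' Leaf inclination
#'
#' Ratio of total (3D) leaf area to projected leaf area: 1 for horizontal
#' leaves, increasing with erectness. Sampling noise can push the raw ratio
#' slightly below 1; such values are floored at 1 and flagged via attribute
#' `floored`. `NA` when the projected area is 0.
#'
#' @param leaf_area 3D leaf area in mm^2.
#' @param projected Projected leaf area in mm^2.
#' @return Dimensionless ratio >= 1, or `NA`.
#' @export
compute_leaf_inclination <- function(leaf_area, projected) {
  if (is.na(projected) || projected <= 0) {
    return(structure(NA_real_, floored = FALSE))
  }
  r <- leaf_area / projected
  structure(max(1, r), floored = r < 1)
}

#' Digital biomass
#'
#' Volumetric proxy for standing biomass: canopy height times 3D leaf area.
#'
#' @param height Canopy height in mm.
#' @param leaf_area 3D leaf area in mm^2.
#' @return Volume in mm^3.
#' @export
compute_digital_biomass <- function(height, leaf_area) {
  stopifnot(height >= 0, leaf_area >= 0)
  height * leaf_area
}

#' Community spectral indices
#'
#' Computes NDVI, NPCI, PSRI, greenness and hue for the plant points of a
#' segmented cloud. With `aggregation = "per_point_mean"` (default) each
#' index is evaluated per point and averaged — arithmetically for
#' NDVI/NPCI/PSRI/greenness and circularly for hue; points with a zero
#' denominator are excluded per index and counted. With
#' `"mean_reflectance"` the channels are averaged first and each index is
#' evaluated once on the mean reflectance. An index undefined at every point
#' is reported `NA`.
#'
#' @param seg A segmented cloud.
#' @param aggregation `"per_point_mean"` or `"mean_reflectance"`.
#' @return A one-row tibble with columns `ndvi, npci, psri, greenness, hue`
#'   and exclusion counts `n_excluded_<index>`.
#' @export
spectral_indices <- function(seg, aggregation = c("per_point_mean", "mean_reflectance")) {
  aggregation <- match.arg(aggregation)
  pl <- plant_points(seg)
  if (nrow(pl) == 0) {
    return(tibble::tibble(
      ndvi = NA_real_, npci = NA_real_, psri = NA_real_,
      greenness = NA_real_, hue = NA_real_,
      n_excluded_ndvi = 0L, n_excluded_npci = 0L, n_excluded_psri = 0L,
      n_excluded_greenness = 0L, n_excluded_hue = 0L
    ))
  }
  if (aggregation == "mean_reflectance") {
    r <- mean(pl$red); g <- mean(pl$green); b <- mean(pl$blue); n <- mean(pl$nir)
    vals <- list(
      ndvi = ndvi(n, r), npci = npci(r, b), psri = psri(r, g, n),
      greenness = greenness(r, g, b), hue = hue_deg(r, g, b)
    )
    excl <- lapply(vals, function(v) if (is.na(v)) nrow(pl) else 0L)
  } else {
    per <- list(
      ndvi = ndvi(pl$nir, pl$red),
      npci = npci(pl$red, pl$blue),
      psri = psri(pl$red, pl$green, pl$nir),
      greenness = greenness(pl$red, pl$green, pl$blue),
      hue = hue_deg(pl$red, pl$green, pl$blue)
    )
    vals <- list(
      ndvi = if (all(is.na(per$ndvi))) NA_real_ else mean(per$ndvi, na.rm = TRUE),
      npci = if (all(is.na(per$npci))) NA_real_ else mean(per$npci, na.rm = TRUE),
      psri = if (all(is.na(per$psri))) NA_real_ else mean(per$psri, na.rm = TRUE),
      greenness = if (all(is.na(per$greenness))) NA_real_ else mean(per$greenness, na.rm = TRUE),
      hue = circular_mean_deg(per$hue)
    )
    excl <- lapply(per, function(v) sum(is.na(v)))
  }
  tibble::tibble(
    ndvi = vals$ndvi, npci = vals$npci, psri = vals$psri,
    greenness = vals$greenness, hue = vals$hue,
    n_excluded_ndvi = as.integer(excl$ndvi),
    n_excluded_npci = as.integer(excl$npci),
    n_excluded_psri = as.integer(excl$psri),
    n_excluded_greenness = as.integer(excl$greenness),
    n_excluded_hue = as.integer(excl$hue)
  )
}

#' Names of the 14 community parameters
#'
#' Nine morphological parameters derived from the 3D structure and five
#' physiological parameters derived from the multispectral channels.
#'
#' @return Character vector of the parameter column names.
#' @export
parameter_names <- function() {
  c(
    "digital_biomass", "height", "height_max", "leaf_area",
    "leaf_area_index", "leaf_area_projected", "leaf_angle",
    "leaf_inclination", "light_penetration_depth",
    "ndvi", "npci", "psri", "greenness", "hue"
  )
}

#' Compute all 14 community parameters of one scan
#'
#' Orchestrates surface reconstruction, the canopy height and light
#' penetration statistics, 3D/projected leaf area, leaf angle and
#' inclination, digital biomass and the five spectral indices for one
#' segmented, soil-calibrated scan. Morphological parameters of an empty
#' canopy are 0 with `flag_empty_canopy` set; undefined physiological
#' indices are `NA`, never 0.
#'
#' Identities that hold exactly by construction:
#' `digital_biomass = height * leaf_area` and
#' `leaf_area_index = leaf_area / sector area`.
#'
#' @param seg A segmented cloud (from [segment_plants()]).
#' @param config A [scan_config()].
#' @param max_edge Mesh pruning edge length in mm, see
#'   [reconstruct_surface()].
#' @param aggregation Spectral aggregation mode, see [spectral_indices()].
#' @param scan_id Optional identifier stored with the row.
#' @return A one-row tibble: `scan_id`, the 14 parameters (mm-based units),
#'   `n_points`, `n_plant_points`, and flags `flag_empty_canopy`,
#'   `flag_degenerate_mesh`, `flag_inclination_floored`.
#' @export
compute_all_parameters <- function(seg, config = scan_config(), max_edge = 5,
                                   aggregation = "per_point_mean",
                                   scan_id = NA_character_) {
  mesh <- reconstruct_surface(seg, max_edge = max_edge)
  height <- compute_height(seg)
  height_max <- compute_height_max(seg)
  leaf_area <- compute_leaf_area(mesh)
  projected <- compute_projected_area(seg, config)
  inclination <- compute_leaf_inclination(leaf_area, projected)
  spectral <- spectral_indices(seg, aggregation = aggregation)
  n_plant <- nrow(plant_points(seg))

  tibble::tibble(
    scan_id = scan_id,
    digital_biomass = compute_digital_biomass(height, leaf_area),
    height = height,
    height_max = height_max,
    leaf_area = leaf_area,
    leaf_area_index = compute_leaf_area_index(leaf_area, config),
    leaf_area_projected = projected,
    leaf_angle = compute_leaf_angle(mesh),
    leaf_inclination = as.numeric(inclination),
    light_penetration_depth = compute_light_penetration(seg),
    ndvi = spectral$ndvi,
    npci = spectral$npci,
    psri = spectral$psri,
    greenness = spectral$greenness,
    hue = spectral$hue,
    n_points = nrow(seg),
    n_plant_points = n_plant,
    flag_empty_canopy = n_plant == 0L,
    flag_degenerate_mesh = mesh$degenerate,
    flag_inclination_floored = isTRUE(attr(inclination, "floored"))
  )
}
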