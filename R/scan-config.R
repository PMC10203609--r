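#' Scan sector configuration
#'
#' Describes the geometry of one scan of a vegetation plot: the footprint of
#' the scanned sector, the vertical range, the lateral sampling resolution and
#' the sensor position used for distance-attenuation correction. The defaults
#' describe a 450 mm x 300 mm x 700 mm sector sampled at sub-millimetre
#' lateral resolution, the standard close-range canopy-scanner setup for
#' 50 x 50 cm grassland plots.
#'
#' The sector ground area `sector_width * sector_length` is the denominator of
#' the leaf area index.
#'
#' @param sector_width,sector_length Footprint of the scanned sector in mm.
#' @param sector_height Vertical extent of the scan in mm above the soil plane.
#' @param grid_resolution Lateral sampling resolution in mm (cell side used
#'   for projected leaf area).
#' @param sensor_height Height of the sensor above the soil plane in mm; must
#'   exceed the tallest vegetation point for attenuation correction.
#' @param attenuation_reference_distance Distance in mm at which reflectance
#'   is taken as uncorrected. The default, `sensor_height - sector_height`,
#'   is the closest possible vegetation-sensor distance, so attenuated values
#'   never exceed their reference value and the correction is invertible.
#' @param band_definitions Named list of `(min, max)` wavelength pairs in nm
#'   for the four sensor bands.
#' @return An object of class `scan_config`.
#' @examples
#' cfg <- scan_config()
#' sector_area(cfg) # 135000 mm^2
#' @export
scan_config <- function(sector_width = 450,
                        sector_length = 300,
                        sector_height = 700,
                        grid_resolution = 1.0,
                        sensor_height = 1000,
                        attenuation_reference_distance = sensor_height - sector_height,
                        band_definitions = list(
                          red = c(620, 645), green = c(530, 540),
                          blue = c(460, 485), nir = c(820, 850)
                        )) {
  stopifnot(
    sector_width > 0, sector_length > 0, sector_height > 0,
    grid_resolution > 0, sensor_height > 0,
    attenuation_reference_distance > 0
  )
  structure(
    list(
      sector_width = sector_width,
      sector_length = sector_length,
      sector_height = sector_height,
      grid_resolution = grid_resolution,
      sensor_height = sensor_height,
      attenuation_reference_distance = attenuation_reference_distance,
      band_definitions = band_definitions
    ),
    class = "scan_config"
  )
}

#' Ground area of the scan sector
#'
#' @param config A [scan_config()].
#' @return Sector ground area in mm^2.
#' @export
sector_area <- function(config) {
  config$sector_width * config$sector_length
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "<scan_config> %g x %g x %g mm sector, %g mm grid, sensor at %g mm (d_ref %g mm)\n",
    x$sector_width, x$sector_length, x$sector_height,
    x$grid_resolution, x$sensor_height, x$attenuation_reference_distance
  ))
  invisible(x)
}
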