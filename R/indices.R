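#' Multispectral vegetation indices
#'
#' Per-point reflectance-ratio indices, vectorised over points. Points where
#' an index's denominator is zero yield `NA` (undefined), never 0:
#'
#' * NDVI  = (NIR - RED) / (NIR + RED), in `[-1, 1]`; bare soil typically
#'   0.1-0.2, healthy dense vegetation > 0.5.
#' * NPCI  = (RED - BLUE) / (RED + BLUE), in `[-1, 1]`; higher red
#'   reflectance (= lower chlorophyll) raises it.
#' * PSRI  = (RED - GREEN) / NIR; rises with senescence (> 0.2 senescent).
#'   As a ratio to NIR it is unbounded for small NIR; values outside
#'   `[-1, 1]` are reported as computed, not clamped.
#' * greenness (green leaf index) = (2 GREEN - RED - BLUE) /
#'   (RED + GREEN + BLUE). Note the formula reaches 2 at pure green;
#'   `normalized = TRUE` divides by (2 GREEN + RED + BLUE) instead, which
#'   bounds it to `[-1, 1]`.
#' * hue = standard RGB -> HSV hue in degrees `[0, 360)`; achromatic points
#'   (RED = GREEN = BLUE) have no hue and yield `NA`.
#'
#' All indices are ratios, so rescaling all channels by a common positive
#' factor leaves them unchanged.
#'
#' @param red,green,blue,nir Reflectance vectors.
#' @param normalized For `greenness()`, use the `[-1, 1]`-bounded variant.
#' @return A numeric vector, `NA` where undefined.
#' @name spectral-indices
NULL

#' @rdname spectral-indices
#' @export
ndvi <- function(nir, red) {
  den <- nir + red
  ifelse(den == 0, NA_real_, (nir - red) / den)
}

#' @rdname spectral-indices
#' @export
npci <- function(red, blue) {
  den <- red + blue
  ifelse(den == 0, NA_real_, (red - blue) / den)
}

#' @rdname spectral-indices
#' @export
psri <- function(red, green, nir) {
  ifelse(nir == 0, NA_real_, (red - green) / nir)
}

#' @rdname spectral-indices
#' @export
greenness <- function(red, green, blue, normalized = FALSE) {
  den <- if (normalized) 2 * green + red + blue else red + green + blue
  ifelse(den == 0, NA_real_, (2 * green - red - blue) / den)
}

#' @rdname spectral-indices
#' @export
hue_deg <- function(red, green, blue) {
  mx <- pmax(red, green, blue)
  mn <- pmin(red, green, blue)
  delta <- mx - mn
  h <- rep(NA_real_, length(mx))
  i <- !is.na(delta) & delta > 0
  r <- red[i]; g <- green[i]; b <- blue[i]; m <- mx[i]; d <- delta[i]
  hi <- numeric(length(d))
  is_r <- m == r
  is_g <- !is_r & m == g
  is_b <- !is_r & !is_g
  hi[is_r] <- ((g[is_r] - b[is_r]) / d[is_r]) %% 6
  hi[is_g] <- (b[is_g] - r[is_g]) / d[is_g] + 2
  hi[is_b] <- (r[is_b] - g[is_b]) / d[is_b] + 4
  h[i] <- hi * 60
  h
}

#' Circular mean of angles in degrees
#'
#' Averages angles as unit phasors, so hues near 0 and 360 average to ~0
#' rather than ~180. `NA` inputs are dropped; an all-`NA` input yields `NA`.
#'
#' @param deg Angles in degrees.
#' @return The circular mean in `[0, 360)`, or `NA`.
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (length(deg) == 0) return(NA_real_)
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  m <- m %% 360
  if (m >= 360) 0 else m  # -eps %% 360 can round to 360 itself
}
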