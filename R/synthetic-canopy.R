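#' Specify a synthetic grassland canopy
#'
#' Describes the statistical population a synthetic canopy is drawn from.
#' Leaves are modelled as planar ellipses so that every ground-truth quantity
#' (area, tilt, height distribution) is available in closed form. The
#' defaults describe a moderately dense, healthy grassland community:
#' leaf centre heights around 300 mm, leaf tilts around 30 degrees from
#' horizontal, and a leaf density giving a leaf area index near 0.9 over the
#' 450 x 300 mm sector.
#'
#' @param leaf_density Leaves per m^2 of sector ground.
#' @param leaf_radius_mean,leaf_radius_sd Effective leaf radius (mm); a leaf
#'   of radius r is an ellipse with semi-axes r times and r over
#'   `leaf_aspect`, so its area is pi r^2.
#' @param leaf_aspect Ellipse elongation (1 = circle).
#' @param height_mean,height_sd Leaf-centre height distribution (mm).
#' @param tilt_mean,tilt_sd Leaf tilt from horizontal (degrees), truncated to
#'   `[0, 85]`.
#' @param chlorophyll,senescence Community physiological state in `[0, 1]`,
#'   see [spectral_model()].
#' @param height_cut If non-`NULL`, a mowing cut height in mm: generated
#'   leaves are shrunk to cut fragments and placed so every apex lies at or
#'   below the cut.
#' @param seed Default seed used by [generate_canopy()].
#' @return A `canopy_spec` list.
#' @export
canopy_spec <- function(leaf_density = 700,
                        leaf_radius_mean = 25, leaf_radius_sd = 6,
                        leaf_aspect = 1.3,
                        height_mean = 300, height_sd = 80,
                        tilt_mean = 30, tilt_sd = 15,
                        chlorophyll = 0.7, senescence = 0.2,
                        height_cut = NULL,
                        seed = NULL) {
  stopifnot(
    leaf_density >= 0, leaf_radius_mean > 0, leaf_radius_sd >= 0,
    leaf_aspect >= 1, height_sd >= 0,
    chlorophyll >= 0, chlorophyll <= 1, senescence >= 0, senescence <= 1,
    is.null(height_cut) || height_cut > 0
  )
  structure(
    list(
      leaf_density = leaf_density,
      leaf_radius_mean = leaf_radius_mean, leaf_radius_sd = leaf_radius_sd,
      leaf_aspect = leaf_aspect,
      height_mean = height_mean, height_sd = height_sd,
      tilt_mean = tilt_mean, tilt_sd = tilt_sd,
      chlorophyll = chlorophyll, senescence = senescence,
      height_cut = height_cut,
      seed = seed
    ),
    class = "canopy_spec"
  )
}

#' Leaf and soil reflectance model
#'
#' A fixed monotone mapping from physiological state to the four sensor
#' channels: near-infrared is constant high (0.80), red decreases with
#' chlorophyll and increases with senescence, green is moderate and decreases
#' with senescence, blue is low. By construction NDVI increases with
#' chlorophyll, NPCI decreases with chlorophyll and PSRI increases with
#' senescence. A fully healthy leaf has NDVI > 0.5 (dense healthy
#' vegetation); the soil signature returned by [soil_signature()] has NDVI in
#' the bare-soil band 0.1-0.2.
#'
#' @param chlorophyll,senescence Values in `[0, 1]` (vectorised).
#' @return A tibble with columns `red, green, blue, nir`.
#' @export
spectral_model <- function(chlorophyll, senescence) {
  if (any(chlorophyll < 0 | chlorophyll > 1) || any(senescence < 0 | senescence > 1)) {
    stop("chlorophyll and senescence must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    red = 0.05 + 0.45 * (1 - chlorophyll) + 0.25 * senescence,
    green = rep_len(0.35, length(chlorophyll)) - 0.15 * senescence,
    blue = rep_len(0.06, max(length(chlorophyll), length(senescence))),
    nir = rep_len(0.80, max(length(chlorophyll), length(senescence)))
  )
}

#' @rdname spectral_model
#' @export
soil_signature <- function() {
  tibble::tibble(red = 0.30, green = 0.28, blue = 0.22, nir = 0.37)
}

#' Scanner model for the virtual canopy scanner
#'
#' Emulates a top-down triangulation scanner: one vertical ray per lateral
#' grid node (plus per-column jitter), recording the highest intersected leaf
#' surface. Because the laser cannot fully penetrate foliage, each occluded
#' deeper surface is recorded only with `penetration_probability`, up to
#' `max_returns` returns per column; a soil return is recorded where nothing
#' is hit. Reflectance is taken from the surface's spectral signature, then
#' distance-attenuated (see [correct_distance_attenuation()]) and perturbed
#' with Gaussian channel noise.
#'
#' @param grid_resolution Lateral ray spacing in mm.
#' @param xy_jitter Uniform per-column jitter half-width in mm.
#' @param penetration_probability Probability that an occluded surface still
#'   yields a return.
#' @param max_returns Maximum returns per column.
#' @param noise_sd Gaussian reflectance noise (per channel).
#' @param attenuation_exponent Inverse-power attenuation exponent (0 = none).
#' @param sensor_height,attenuation_reference_distance Geometry shared with
#'   [scan_config()].
#' @return A `scanner_model` list.
#' @export
scanner_model <- function(grid_resolution = 1, xy_jitter = 0.2,
                          penetration_probability = 0.5, max_returns = 3,
                          noise_sd = 0.001, attenuation_exponent = 2,
                          sensor_height = 1000,
                          attenuation_reference_distance = 300) {
  stopifnot(
    grid_resolution > 0, xy_jitter >= 0,
    penetration_probability >= 0, penetration_probability <= 1,
    max_returns >= 1, noise_sd >= 0
  )
  structure(
    list(
      grid_resolution = grid_resolution, xy_jitter = xy_jitter,
      penetration_probability = penetration_probability,
      max_returns = max_returns, noise_sd = noise_sd,
      attenuation_exponent = attenuation_exponent,
      sensor_height = sensor_height,
      attenuation_reference_distance = attenuation_reference_distance
    ),
    class = "scanner_model"
  )
}

#' @rdname scanner_model
#' @param scanner A `scanner_model`.
#' @param grid_resolution_config Grid resolution for the derived config
#'   (defaults to the scanner's).
#' @return `as_scan_config()`: the matching [scan_config()] for processing
#'   clouds simulated with `scanner`.
#' @export
as_scan_config <- function(scanner, grid_resolution_config = scanner$grid_resolution) {
  scan_config(
    grid_resolution = grid_resolution_config,
    sensor_height = scanner$sensor_height,
    attenuation_reference_distance = scanner$attenuation_reference_distance
  )
}

weighted_top_fraction_mean <- function(z, w, frac) {
  if (length(z) == 0) return(NA_real_)
  ord <- order(z, decreasing = TRUE)
  z <- z[ord]; w <- w[ord]
  target <- frac * sum(w)
  cum <- cumsum(w)
  k <- which(cum >= target)[1]
  w_used <- w[seq_len(k)]
  w_used[k] <- w_used[k] - (cum[k] - target)  # fractional boundary sample
  sum(z[seq_len(k)] * w_used) / sum(w_used)
}

#' Generate a synthetic canopy scene with analytic ground truth
#'
#' Draws `Poisson(leaf_density x sector area)` planar elliptic leaves with
#' uniform centres, truncated-normal radii, heights and tilts, and uniform
#' azimuths, per [canopy_spec()]. Ground truth comprises the analytic total
#' leaf area (`sum of pi a b`), the area-weighted mean tilt, and the
#' projected-area-weighted mean height of the top decile of the leaf surface
#' (computed by dense deterministic sampling of each ellipse, independent of
#' any scanner).
#'
#' @param spec A [canopy_spec()].
#' @param seed Random seed (defaults to `spec$seed`); fixed seeds reproduce
#'   scenes exactly.
#' @param config A [scan_config()] providing the sector bounds.
#' @return A list with elements `scene` (a `canopy_scene`) and `truth` (a
#'   `canopy_truth` with `total_leaf_area`, `true_mean_tilt`,
#'   `true_height_top_decile`, `n_leaves`).
#' @export
generate_canopy <- function(spec, seed = spec$seed, config = scan_config()) {
  stopifnot(inherits(spec, "canopy_spec"))
  run <- function() {
    area_m2 <- sector_area(config) / 1e6
    n <- stats::rpois(1, spec$leaf_density * area_m2)
    if (n == 0) {
      leaves <- tibble::tibble(
        cx = numeric(), cy = numeric(), cz = numeric(),
        a = numeric(), b = numeric(), tilt = numeric(), azimuth = numeric(),
        nx = numeric(), ny = numeric(), nz = numeric(),
        ux = numeric(), uy = numeric(), uz = numeric(),
        vx = numeric(), vy = numeric(), vz = numeric(),
        chlorophyll = numeric(), senescence = numeric()
      )
    } else {
      r <- pmax(3, stats::rnorm(n, spec$leaf_radius_mean, spec$leaf_radius_sd))
      a <- r * spec$leaf_aspect
      b <- r / spec$leaf_aspect
      tilt <- pmin(85, pmax(0, stats::rnorm(n, spec$tilt_mean, spec$tilt_sd)))
      azim <- stats::runif(n, 0, 2 * pi)
      st <- sin(tilt * pi / 180); ct <- cos(tilt * pi / 180)
      # normal, and in-plane axes: u horizontal (strike), v up-slope (dip)
      nx <- st * cos(azim); ny <- st * sin(azim); nz <- ct
      ux <- -sin(azim); uy <- cos(azim); uz <- rep(0, n)
      vx <- -ct * cos(azim); vy <- -ct * sin(azim); vz <- st
      ez <- b * st  # vertical half-extent (a lies along the horizontal axis)
      if (!is.null(spec$height_cut)) {
        # mowing fragments: shrink blades so each apex fits under the cut
        shrink <- pmin(1, 0.45 * spec$height_cut / pmax(ez, 1e-9))
        a <- a * shrink; b <- b * shrink; ez <- ez * shrink
        cz <- stats::runif(n, ez, spec$height_cut - ez)
      } else {
        cz <- pmax(ez, stats::rnorm(n, spec$height_mean, spec$height_sd))
      }
      leaves <- tibble::tibble(
        cx = stats::runif(n, 0, config$sector_width),
        cy = stats::runif(n, 0, config$sector_length),
        cz = cz, a = a, b = b, tilt = tilt, azimuth = azim,
        nx = nx, ny = ny, nz = nz, ux = ux, uy = uy, uz = uz,
        vx = vx, vy = vy, vz = vz,
        chlorophyll = pmin(1, pmax(0, stats::rnorm(n, spec$chlorophyll, 0.03))),
        senescence = pmin(1, pmax(0, stats::rnorm(n, spec$senescence, 0.03)))
      )
    }
    scene <- structure(
      list(leaves = leaves, config = config, soil = soil_signature(), spec = spec),
      class = "canopy_scene"
    )
    list(scene = scene, truth = scene_truth(scene))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# deterministic dense surface sampling for the height ground truth
scene_truth <- function(scene) {
  lv <- scene$leaves
  areas <- pi * lv$a * lv$b
  if (nrow(lv) == 0) {
    return(structure(
      list(total_leaf_area = 0, true_mean_tilt = NA_real_,
           true_height_top_decile = NA_real_, n_leaves = 0L),
      class = "canopy_truth"
    ))
  }
  golden <- pi * (3 - sqrt(5))
  cfg <- scene$config
  zs <- vector("list", nrow(lv))
  ws <- vector("list", nrow(lv))
  for (i in seq_len(nrow(lv))) {
    m <- max(256L, ceiling(areas[i] / 4))
    k <- seq_len(m)
    rho <- sqrt((k - 0.5) / m)
    th <- golden * k
    sa <- lv$a[i] * rho * cos(th)  # in-plane coordinates of the sample
    tb <- lv$b[i] * rho * sin(th)
    px <- lv$cx[i] + sa * lv$ux[i] + tb * lv$vx[i]
    py <- lv$cy[i] + sa * lv$uy[i] + tb * lv$vy[i]
    # only surface inside the sector is scannable and counts for the
    # sector-level height distribution
    inside <- px >= 0 & px <= cfg$sector_width & py >= 0 & py <= cfg$sector_length
    zs[[i]] <- lv$cz[i] + tb[inside] * lv$vz[i]
    ws[[i]] <- rep(areas[i] * lv$nz[i] / m, sum(inside))  # projected-area weights
  }
  structure(
    list(
      total_leaf_area = sum(areas),
      true_mean_tilt = stats::weighted.mean(lv$tilt, areas),
      true_height_top_decile = weighted_top_fraction_mean(unlist(zs), unlist(ws), 0.10),
      n_leaves = nrow(lv)
    ),
    class = "canopy_truth"
  )
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf(
    "<canopy_scene> %d leaves over %g x %g mm sector\n",
    nrow(x$leaves), x$config$sector_width, x$config$sector_length
  ))
  invisible(x)
}

#' Simulate a scan of a canopy scene
#'
#' Casts one vertical ray per grid column (with per-column jitter), records
#' the highest intersected leaf, records each occluded deeper surface with
#' the scanner's penetration probability (up to `max_returns` per column),
#' and records a soil return where nothing is hit. Reflectance comes from
#' each surface's spectral signature, then distance attenuation and Gaussian
#' channel noise are applied. Reproducible for a fixed seed.
#'
#' @param scene A `canopy_scene` from [generate_canopy()].
#' @param scanner A [scanner_model()].
#' @param seed Random seed.
#' @param soil_z Height of the soil plane in mm (non-zero emulates an
#'   uncalibrated scan; the whole scene shifts with it).
#' @return A list: `cloud` (point-cloud tibble), `truth` (the scene's
#'   `canopy_truth` extended with `visible_leaf_area` after occlusion and a
#'   `per_point` tibble of surface ids and pre-attenuation, pre-noise
#'   reflectance).
#' @export
simulate_scan <- function(scene, scanner = scanner_model(), seed = NULL, soil_z = 0) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(scanner, "scanner_model"))
  run <- function() {
    cfg <- scene$config
    res <- scanner$grid_resolution
    nx <- max(1L, round(cfg$sector_width / res))
    ny <- max(1L, round(cfg$sector_length / res))
    xc <- (seq_len(nx) - 0.5) * res
    yc <- (seq_len(ny) - 0.5) * res
    ncol_ <- nx * ny
    jx <- if (scanner$xy_jitter > 0) stats::runif(ncol_, -scanner$xy_jitter, scanner$xy_jitter) else numeric(ncol_)
    jy <- if (scanner$xy_jitter > 0) stats::runif(ncol_, -scanner$xy_jitter, scanner$xy_jitter) else numeric(ncol_)
    colx <- rep(xc, times = ny) + jx
    coly <- rep(yc, each = nx) + jy

    lv <- scene$leaves
    hit_col <- integer(0); hit_leaf <- integer(0); hit_z <- numeric(0)
    if (nrow(lv) > 0) {
      jm <- scanner$xy_jitter
      acc <- vector("list", nrow(lv))
      for (i in seq_len(nrow(lv))) {
        ex <- sqrt((lv$a[i] * lv$ux[i])^2 + (lv$b[i] * lv$vx[i])^2)
        ey <- sqrt((lv$a[i] * lv$uy[i])^2 + (lv$b[i] * lv$vy[i])^2)
        ixs <- which(abs(xc - lv$cx[i]) <= ex + jm + res)
        iys <- which(abs(yc - lv$cy[i]) <= ey + jm + res)
        if (length(ixs) == 0 || length(iys) == 0) { acc[[i]] <- NULL; next }
        ids <- rep(ixs, times = length(iys)) + (rep(iys, each = length(ixs)) - 1L) * nx
        dx <- colx[ids] - lv$cx[i]
        dy <- coly[ids] - lv$cy[i]
        z <- lv$cz[i] - (lv$nx[i] * dx + lv$ny[i] * dy) / lv$nz[i]
        dz <- z - lv$cz[i]
        s <- (dx * lv$ux[i] + dy * lv$uy[i] + dz * lv$uz[i]) / lv$a[i]
        t <- (dx * lv$vx[i] + dy * lv$vy[i] + dz * lv$vz[i]) / lv$b[i]
        inside <- s * s + t * t <= 1
        if (any(inside)) {
          acc[[i]] <- list(col = ids[inside], leaf = rep(i, sum(inside)), z = z[inside])
        }
      }
      acc <- acc[!vapply(acc, is.null, logical(1))]
      if (length(acc) > 0) {
        hit_col <- unlist(lapply(acc, `[[`, "col"))
        hit_leaf <- unlist(lapply(acc, `[[`, "leaf"))
        hit_z <- unlist(lapply(acc, `[[`, "z"))
      }
    }

    # order hits per column by depth; keep first return, deeper ones with
    # the penetration probability, at most max_returns per column
    if (length(hit_col) > 0) {
      ord <- order(hit_col, -hit_z)
      hit_col <- hit_col[ord]; hit_leaf <- hit_leaf[ord]; hit_z <- hit_z[ord]
      runs <- rle(hit_col)$lengths
      rank <- sequence(runs)
      is_first <- rank == 1L
      keep <- is_first | stats::runif(length(rank)) < scanner$penetration_probability
      hit_col <- hit_col[keep]; hit_leaf <- hit_leaf[keep]; hit_z <- hit_z[keep]
      is_first <- is_first[keep]
      runs <- rle(hit_col)$lengths
      rank <- sequence(runs)
      keep2 <- rank <= scanner$max_returns
      hit_col <- hit_col[keep2]; hit_leaf <- hit_leaf[keep2]
      hit_z <- hit_z[keep2]; is_first <- is_first[keep2]
    } else {
      is_first <- logical(0)
    }

    any_hit <- logical(ncol_)
    any_hit[hit_col] <- TRUE
    soil_cols <- which(!any_hit)

    col_id <- c(hit_col, soil_cols)
    surface <- c(hit_leaf, rep(0L, length(soil_cols)))
    z <- c(hit_z, rep(0, length(soil_cols))) + soil_z
    ordp <- order(col_id, -z)
    col_id <- col_id[ordp]; surface <- surface[ordp]; z <- z[ordp]

    n_pts <- length(col_id)
    sig <- matrix(0, nrow = n_pts, ncol = 4,
                  dimnames = list(NULL, cloud_channels))
    leaf_rows <- surface > 0
    if (any(leaf_rows)) {
      ls <- spectral_model(lv$chlorophyll[surface[leaf_rows]],
                           lv$senescence[surface[leaf_rows]])
      sig[leaf_rows, ] <- as.matrix(ls[, cloud_channels])
    }
    if (any(!leaf_rows)) {
      sig[!leaf_rows, ] <- matrix(as.numeric(scene$soil[1, cloud_channels]),
                                  nrow = sum(!leaf_rows), ncol = 4, byrow = TRUE)
    }
    true_sig <- sig

    if (scanner$attenuation_exponent != 0) {
      d <- scanner$sensor_height - z
      f <- (scanner$attenuation_reference_distance / d)^scanner$attenuation_exponent
      sig <- sig * f
    }
    if (scanner$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(n_pts * 4, 0, scanner$noise_sd), ncol = 4)
    }
    sig <- pmin(pmax(sig, 0), 1)  # argument order keeps the matrix dims

    cloud <- pointcloud(
      x = colx[col_id], y = coly[col_id], z = z,
      red = sig[, "red"], green = sig[, "green"],
      blue = sig[, "blue"], nir = sig[, "nir"]
    )

    # visible 3D area per leaf from exact first-return geometry: each first
    # return stands for one column footprint on the tilted surface
    visible <- 0
    if (nrow(lv) > 0 && any(is_first)) {
      counts <- tabulate(hit_leaf[is_first], nbins = nrow(lv))
      visible <- sum(pmin(counts * res^2 / lv$nz, pi * lv$a * lv$b))
    }
    truth <- scene_truth(scene)
    truth$visible_leaf_area <- visible
    truth$per_point <- tibble::tibble(
      point_id = cloud$point_id,
      surface_id = surface,
      red0 = true_sig[, "red"], green0 = true_sig[, "green"],
      blue0 = true_sig[, "blue"], nir0 = true_sig[, "nir"]
    )
    list(cloud = cloud, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
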