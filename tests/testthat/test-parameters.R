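test_that("surface reconstruction handles hand-built geometries", {
  sq <- as_plant(pointcloud(
    x = c(0, 10, 0, 10), y = c(0, 0, 10, 10), z = 0,
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
  mesh <- reconstruct_surface(sq, max_edge = 20)
  expect_identical(nrow(mesh$triangles), 2L)
  expect_equal(compute_leaf_area(mesh), 100)
  expect_equal(mesh$normal[, 3], c(1, 1))

  # all edges >= 10 mm, diagonal ~14.1: everything pruned at max_edge 5
  pruned <- reconstruct_surface(sq, max_edge = 5)
  expect_identical(nrow(pruned$triangles), 0L)
  expect_equal(compute_leaf_area(pruned), 0)

  collinear <- as_plant(pointcloud(
    x = c(0, 1, 2), y = c(0, 1, 2), z = 0,
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
  expect_true(reconstruct_surface(collinear)$degenerate)
  expect_true(reconstruct_surface(sq[1:2, ])$degenerate)
})

test_that("duplicate (x, y) positions keep only the surface return", {
  two_layers <- as_plant(pointcloud(
    x = c(0, 10, 0, 10, 0), y = c(0, 0, 10, 10, 0), z = c(5, 5, 5, 5, 1),
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
  mesh <- reconstruct_surface(two_layers, max_edge = 20)
  expect_identical(nrow(mesh$vertices), 4L)
  expect_true(all(mesh$vertices[, "z"] == 5))
})

test_that("Delaunay core agrees with an independent triangulation library", {
  skip_if_not_installed("interp")
  withr::with_seed(42, {
    x <- runif(500, 0, 100)
    y <- runif(500, 0, 100)
  })
  mine <- dwcp:::.delaunay_xy(x, y)
  ref <- interp::triangles(interp::tri.mesh(x, y))[, 1:3]
  canon <- function(m) {
    m <- t(apply(m, 1, sort))
    m[order(m[, 1], m[, 2], m[, 3]), ]
  }
  expect_identical(canon(mine), canon(unname(ref)))
})

test_that("height statistics match sort-based oracles", {
  seg <- plant_z_cloud(1:100)
  expect_equal(compute_height(seg), mean(91:100)) # 95.5
  expect_equal(compute_height_max(seg), 100)
  expect_equal(compute_light_penetration(seg), mean(91:100) - mean(1:20)) # 85

  const <- plant_z_cloud(rep(300, 50))
  expect_equal(compute_height(const), 300)
  expect_equal(compute_height_max(const), 300)
  expect_equal(compute_light_penetration(const), 0)

  single <- plant_z_cloud(42)
  expect_equal(compute_height(single), 42)

  layered <- plant_z_cloud(c(rep(100, 60), rep(300, 40)))
  expect_equal(compute_light_penetration(layered), 200)

  # empty canopy: morphological zeros
  none <- plant_z_cloud(1:10)
  none$label[] <- "soil"
  expect_equal(compute_height(none), 0)
  expect_equal(compute_height_max(none), 0)
  expect_equal(compute_light_penetration(none), 0)
})

test_that("projected area counts occupied grid cells", {
  cfg <- scan_config(grid_resolution = 1)
  one_cell <- as_plant(pointcloud(
    x = runif(100, 3.1, 3.9), y = runif(100, 7.1, 7.9), z = 10,
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
  expect_equal(compute_projected_area(one_cell, cfg), 1)

  block <- as_plant(pointcloud(
    x = rep(seq(0.5, 9.5, 1), 10), y = rep(seq(0.5, 9.5, 1), each = 10), z = 10,
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
  expect_equal(compute_projected_area(block, cfg), 100)

  none <- block
  none$label[] <- "soil"
  expect_equal(compute_projected_area(none, cfg), 0)
})

test_that("leaf area index is area over sector area", {
  cfg <- scan_config() # 450 x 300
  expect_equal(compute_leaf_area_index(67500, cfg), 0.5)
  expect_equal(compute_leaf_area_index(0, cfg), 0)
  expect_equal(compute_leaf_area_index(sector_area(cfg), cfg), 1)
})

test_that("leaf angle is the area-weighted angle to the perpendicular", {
  flat <- reconstruct_surface(tilted_plane_cloud(0, extent = 30), max_edge = 5)
  expect_equal(compute_leaf_angle(flat), 90, tolerance = 1e-6)

  tilted <- reconstruct_surface(tilted_plane_cloud(30, extent = 30), max_edge = 5)
  expect_equal(compute_leaf_angle(tilted), 60, tolerance = 0.01)

  # two equal-area planes at 90 (horizontal) and 0 (vertical) average to 45
  mesh <- structure(
    list(
      vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3),
      area = c(50, 50),
      normal = rbind(c(0, 0, 1), c(1, 0, 0)),
      max_edge = 5, degenerate = FALSE
    ),
    class = "triangle_mesh"
  )
  expect_equal(compute_leaf_angle(mesh), 45)

  empty <- reconstruct_surface(plant_z_cloud(numeric(0)))
  expect_true(is.na(compute_leaf_angle(empty)))
})

test_that("leaf inclination is floored at 1 and undefined for zero projection", {
  expect_equal(as.numeric(compute_leaf_inclination(200, 100)), 2)
  expect_equal(as.numeric(compute_leaf_inclination(100, 100)), 1)
  floored <- compute_leaf_inclination(95, 100)
  expect_equal(as.numeric(floored), 1)
  expect_true(attr(floored, "floored"))
  expect_true(is.na(compute_leaf_inclination(100, 0)))
})

test_that("tilted-plane oracle: angle, inclination and area vs analytic geometry", {
  cfg <- scan_config(grid_resolution = 1)
  for (theta in c(0, 15, 30, 45, 60)) {
    seg <- tilted_plane_cloud(theta, extent = 200, spacing = 1)
    mesh <- reconstruct_surface(seg, max_edge = 5)
    area <- compute_leaf_area(mesh)
    projected <- compute_projected_area(seg, cfg)
    expect_lt(abs(compute_leaf_angle(mesh) - (90 - theta)), 1)
    expect_lt(abs(as.numeric(compute_leaf_inclination(area, projected)) -
                    1 / cos(theta * pi / 180)),
              0.02 / cos(theta * pi / 180))
    expect_lt(abs(area - projected / cos(theta * pi / 180)) /
                (projected / cos(theta * pi / 180)), 0.02)
  }
})

test_that("digital biomass is height times leaf area", {
  expect_equal(compute_digital_biomass(0, 5000), 0)
  expect_equal(compute_digital_biomass(200, 50000), 1e7)
  expect_error(compute_digital_biomass(-1, 10))
})

test_that("per-point spectral indices match their closed forms", {
  expect_equal(ndvi(0.6, 0.2), 0.5)
  expect_equal(npci(0.2, 0.2), 0)
  expect_equal(psri(0.3, 0.1, 0.8), 0.25)
  expect_equal(greenness(0, 1, 0), 2) # pure green under the printed formula
  expect_equal(hue_deg(0, 1, 0), 120)
  expect_equal(greenness(0.3, 0.3, 0.3), 0)
  expect_true(is.na(hue_deg(0.3, 0.3, 0.3))) # achromatic: no hue
  expect_true(is.na(ndvi(0, 0)))
  expect_true(is.na(psri(0.1, 0.2, 0)))
})

test_that("hue agrees with grDevices::rgb2hsv", {
  withr::with_seed(8, {
    r <- runif(1000); g <- runif(1000); b <- runif(1000)
  })
  mine <- hue_deg(r, g, b)
  ref <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)[1, ] * 360
  chroma <- pmax(r, g, b) > pmin(r, g, b)
  expect_equal(unname(mine[chroma]), unname(ref[chroma]), tolerance = 1e-9)
})

test_that("community spectral indices average per point, hue circularly", {
  cl <- as_plant(pointcloud(
    x = 1:2, y = 1, z = 10,
    red = c(0.2, 0.4), green = c(0.3, 0.3), blue = c(0.1, 0.1),
    nir = c(0.6, 0.8)
  ))
  idx <- spectral_indices(cl)
  expect_equal(idx$ndvi, mean(c(ndvi(0.6, 0.2), ndvi(0.8, 0.4))))
  expect_equal(idx$npci, mean(c(npci(0.2, 0.1), npci(0.4, 0.1))))

  # circular hue mean: 350 and 10 degrees average to 0, not 180
  reds <- as_plant(pointcloud(
    x = 1:2, y = 1, z = 10,
    red = c(1, 1), green = c(0, 1 / 6), blue = c(1 / 6, 0), nir = 0.5
  ))
  expect_equal(hue_deg(reds$red, reds$green, reds$blue), c(350, 10))
  expect_equal(spectral_indices(reds)$hue, 0, tolerance = 1e-9)

  # all points achromatic: hue is missing, not 0
  gray <- as_plant(pointcloud(x = 1:2, y = 1, z = 10, red = 0.3,
                              green = 0.3, blue = 0.3, nir = 0.6))
  idxg <- spectral_indices(gray)
  expect_true(is.na(idxg$hue))
  expect_identical(idxg$n_excluded_hue, 2L)
  expect_equal(idxg$greenness, 0)
})

test_that("spectral indices are invariant under channel rescaling", {
  cl <- random_cloud(500, seed = 13)
  seg <- as_plant(cl)
  half <- seg
  for (ch in c("red", "green", "blue", "nir")) half[[ch]] <- half[[ch]] * 0.5
  a <- spectral_indices(seg)
  b <- spectral_indices(half)
  for (col in c("ndvi", "npci", "psri", "greenness", "hue")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-12)
  }
})

test_that("compute_all_parameters satisfies its structural invariants", {
  gen <- generate_canopy(canopy_spec(leaf_density = 120), seed = 31)
  sc <- scanner_model(grid_resolution = 2)
  sim <- simulate_scan(gen$scene, sc, seed = 32)
  cfg <- as_scan_config(sc)
  seg <- correct_distance_attenuation(sim$cloud, cfg) |> segment_plants()
  par <- compute_all_parameters(seg, cfg)

  expect_identical(par$digital_biomass, par$height * par$leaf_area)
  expect_identical(par$leaf_area_index, par$leaf_area / sector_area(cfg))
  expect_gte(par$leaf_inclination, 1)
  expect_gte(par$height_max, par$height)
  expect_gte(par$light_penetration_depth, 0)
  expect_true(par$leaf_angle >= 0 && par$leaf_angle <= 90)
  expect_true(par$hue >= 0 && par$hue < 360)
  expect_true(abs(par$ndvi) <= 1 && abs(par$npci) <= 1)
  expect_gte(par$leaf_area, par$leaf_area_projected)
})

test_that("a flat-lawn scene yields its known height, penetration and angle", {
  # dense flat horizontal leaves all centred at 150 mm
  spec <- canopy_spec(leaf_density = 400, height_mean = 150, height_sd = 0,
                      tilt_mean = 0, tilt_sd = 0)
  gen <- generate_canopy(spec, seed = 41)
  sc <- scanner_model(grid_resolution = 1.5)
  sim <- simulate_scan(gen$scene, sc, seed = 42)
  cfg <- as_scan_config(sc)
  seg <- correct_distance_attenuation(sim$cloud, cfg) |> segment_plants()
  par <- compute_all_parameters(seg, cfg, max_edge = 5)
  expect_lt(abs(par$height - 150), 1)
  expect_lt(par$light_penetration_depth, 1)
  expect_gt(par$leaf_angle, 89)
})

test_that("an empty plant set gives zero morphology, missing spectra and flags", {
  soil_only <- plant_z_cloud(1:20)
  soil_only$label[] <- "soil"
  par <- compute_all_parameters(soil_only)
  expect_true(par$flag_empty_canopy)
  expect_identical(par$height, 0)
  expect_identical(par$digital_biomass, 0)
  expect_identical(par$leaf_area, 0)
  expect_true(is.na(par$ndvi))
  expect_true(is.na(par$hue))
  expect_true(is.na(par$leaf_angle))
})

test_that("truncating a canopy never increases height-based parameters", {
  gen <- generate_canopy(canopy_spec(leaf_density = 150), seed = 51)
  sc <- scanner_model(grid_resolution = 2)
  sim <- simulate_scan(gen$scene, sc, seed = 52)
  cfg <- as_scan_config(sc)
  seg <- correct_distance_attenuation(sim$cloud, cfg) |> segment_plants()
  cuts <- c(Inf, 400, 250, 120, 50)
  prev <- NULL
  for (cut in cuts) {
    clipped <- seg[!(seg$label == "plant" & seg$z > cut), ]
    par <- compute_all_parameters(clipped, cfg)
    if (!is.null(prev)) {
      expect_lte(par$height, prev$height + 1e-9)
      expect_lte(par$height_max, prev$height_max + 1e-9)
      expect_lte(par$digital_biomass, prev$digital_biomass + 1e-9)
      expect_lte(par$light_penetration_depth, prev$light_penetration_depth + 1e-9)
    }
    prev <- par
  }
})

test_that("percentile statistics match exhaustive oracles on integer lists", {
  withr::with_seed(7, {
    for (i in 1:20) {
      z <- sample.int(1000, sample(c(1, 5, 50, 1000, 9999), 1), replace = TRUE)
      seg <- plant_z_cloud(z)
      zs <- sort(z, decreasing = TRUE)
      expect_identical(compute_height(seg), mean(zs[seq_len(ceiling(0.1 * length(z)))]))
      expect_identical(compute_height_max(seg), as.numeric(max(z)))
      oracle_pen <- max(0, mean(zs[seq_len(ceiling(0.1 * length(z)))]) -
                          mean(sort(z)[seq_len(ceiling(0.2 * length(z)))]))
      expect_identical(compute_light_penetration(seg), oracle_pen)
    }
  })
})
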