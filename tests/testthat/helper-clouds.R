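# Fixtures are built in code: random clouds, analytic tilted planes, and
# small segmented clouds with known geometry.

random_cloud <- function(n, seed = 1) {
  withr::with_seed(seed, {
    pointcloud(
      x = runif(n, 0, 450), y = runif(n, 0, 300), z = runif(n, 0, 700),
      red = runif(n), green = runif(n), blue = runif(n), nir = runif(n)
    )
  })
}

# A densely sampled plane tilted theta degrees from horizontal, sampled on a
# regular (x, y) grid like a top-down scanner: z = x * tan(theta).
tilted_plane_cloud <- function(theta_deg, extent = 200, spacing = 1) {
  g <- expand.grid(
    x = seq(spacing / 2, extent - spacing / 2, by = spacing),
    y = seq(spacing / 2, extent - spacing / 2, by = spacing)
  )
  cl <- pointcloud(
    x = g$x, y = g$y, z = g$x * tan(theta_deg * pi / 180),
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  )
  as_plant(cl)
}

# mark every point as plant without running segmentation
as_plant <- function(cloud) {
  cloud$label <- factor("plant", levels = c("plant", "soil", "noise"))
  cloud
}

plant_z_cloud <- function(z) {
  n <- length(z)
  as_plant(pointcloud(
    x = seq_len(n), y = 0, z = z,
    red = 0.1, green = 0.3, blue = 0.05, nir = 0.8
  ))
}
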