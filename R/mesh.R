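#' Reconstruct the canopy surface as a 2.5D triangle mesh
#'
#' Triangulates the plant points of a segmented cloud by Delaunay
#' triangulation of their (x, y) projection, lifts the triangles to 3D, and
#' prunes every triangle with a 3D edge longer than `max_edge`. Edge pruning
#' prevents the mesh from bridging between separate leaves and across gaps in
#' the canopy. Triangle areas and upward-oriented unit normals are computed
#' from the lifted geometry; the summed triangle area is the 3D leaf area.
#'
#' Multiple returns along one vertical scan line share an (x, y) position and
#' cannot coexist in a 2.5D surface; for duplicated (x, y) positions only the
#' highest point (the canopy surface return) enters the mesh.
#'
#' @param seg A segmented cloud (from [segment_plants()]).
#' @param max_edge Maximum allowed 3D edge length in mm (default 5).
#' @return A `triangle_mesh`: list with `vertices` (matrix of the plant
#'   points used), `triangles` (index triples into `vertices`), `area` (mm^2
#'   per triangle), `normal` (unit rows, non-negative z), `max_edge`, and a
#'   logical `degenerate` flag set when fewer than 3 non-collinear plant
#'   points exist (the mesh is then empty and downstream areas are 0).
#' @export
reconstruct_surface <- function(seg, max_edge = 5) {
  pl <- plant_points(seg)
  empty <- function(degenerate) {
    structure(
      list(
        vertices = matrix(numeric(0), ncol = 3,
                          dimnames = list(NULL, c("x", "y", "z"))),
        triangles = matrix(integer(0), ncol = 3),
        area = numeric(0),
        normal = matrix(numeric(0), ncol = 3),
        max_edge = max_edge,
        degenerate = degenerate
      ),
      class = "triangle_mesh"
    )
  }
  if (nrow(pl) < 3) return(empty(TRUE))

  # one surface return per (x, y): keep the highest
  ord <- order(pl$x, pl$y, -pl$z)
  pl <- pl[ord, ]
  dup <- duplicated(pl[, c("x", "y")])
  pl <- pl[!dup, ]
  if (nrow(pl) < 3) return(empty(TRUE))

  xy <- cbind(pl$x, pl$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2) return(empty(TRUE))

  tri <- .delaunay_xy(pl$x, pl$y)
  if (nrow(tri) == 0) return(empty(TRUE))

  v <- cbind(x = pl$x, y = pl$y, z = pl$z)
  p1 <- v[tri[, 1], , drop = FALSE]
  p2 <- v[tri[, 2], , drop = FALSE]
  p3 <- v[tri[, 3], , drop = FALSE]
  e12 <- p2 - p1
  e13 <- p3 - p1
  e23 <- p3 - p2
  len2 <- function(m) sqrt(rowSums(m^2))
  keep <- len2(e12) <= max_edge & len2(e13) <= max_edge & len2(e23) <= max_edge

  cr <- cbind(
    e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
    e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
    e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1]
  )
  nrm <- len2(cr)
  keep <- keep & nrm > 1e-12
  tri <- tri[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]
  nrm <- nrm[keep]
  normal <- cr / nrm
  flip <- normal[, 3] < 0
  normal[flip, ] <- -normal[flip, , drop = FALSE]

  structure(
    list(
      vertices = v,
      triangles = tri,
      area = nrm / 2,
      normal = normal,
      max_edge = max_edge,
      degenerate = FALSE
    ),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf(
    "<triangle_mesh> %d vertices, %d triangles, area %.1f mm^2 (max_edge %g mm)%s\n",
    nrow(x$vertices), nrow(x$triangles), sum(x$area), x$max_edge,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @describeIn reconstruct_surface One row per triangle with its vertex
#'   indices, area and normal components.
#' @param x A `triangle_mesh`.
#' @param ... Unused.
#' @method tidy triangle_mesh
#' @export
tidy.triangle_mesh <- function(x, ...) {
  tibble::tibble(
    v1 = x$triangles[, 1], v2 = x$triangles[, 2], v3 = x$triangles[, 3],
    area = x$area,
    nx = x$normal[, 1], ny = x$normal[, 2], nz = x$normal[, 3]
  )
}
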