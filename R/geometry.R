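#' Geometry of the unit sphere and its icosahedral chart
#'
#' The network discretises the sphere by the 12 vertices of a regular
#' icosahedron. Each vertex carries a tangent frame obtained by parallel
#' transport of a reference frame at a base vertex along the minimizing
#' geodesic; tangent-plane kernels are sampled on a polar grid expressed in
#' those frames. All points are ambient unit 3-vectors; tangent vectors are
#' either ambient 3-vectors orthogonal to their base point or 2-vectors of
#' frame coordinates, in arc-length units (radians).
#'
#' @name sphere-geometry
NULL

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an axis (Rodrigues formula)
#'
#' @param axis rotation axis, any nonzero 3-vector (normalised internally).
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Exponential map on the sphere
#'
#' Follows the geodesic leaving `x` with initial velocity `v` for unit time:
#' `cos(|v|) x + sin(|v|) v/|v|`. The zero vector maps to `x` itself.
#'
#' @param x unit 3-vector (base point).
#' @param v ambient tangent 3-vector at `x` (orthogonal to `x`); its norm is
#'   the arc length travelled.
#' @return Unit 3-vector.
#' @export
exp_map <- function(x, v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(x)
  .unit(cos(nv) * x + sin(nv) * (v / nv))
}

#' Logarithm map on the sphere
#'
#' Inverse of [exp_map()] on the sphere minus the antipode of `x`; returns
#' the ambient tangent vector at `x` pointing towards `y` with norm equal to
#' the geodesic distance `arccos(x . y)`.
#'
#' @param x,y unit 3-vectors; `y` must not be antipodal to `x`.
#' @return Ambient tangent 3-vector at `x`.
#' @export
log_map <- function(x, y) {
  d <- max(-1, min(1, sum(x * y)))
  if (d < -1 + 1e-12)
    stop("log_map is undefined at the antipode (cut locus)")
  theta <- acos(d)
  if (theta < 1e-14) return(c(0, 0, 0))
  w <- y - d * x
  theta * .unit(w)
}

# Canonical golden-ratio icosahedron, rotated so vertex 1 sits at (0,0,1).
# The embedding is fixed; `base_index` only selects which vertex anchors the
# parallel-transported frames.
.icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  raw <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  V <- raw / sqrt(1 + phi^2)
  # rotate vertex 1 onto the north pole
  v0 <- V[1, ]
  z <- c(0, 0, 1)
  axis <- .cross3(v0, z)
  R <- rotation_about_axis(axis, acos(max(-1, min(1, sum(v0 * z)))))
  V <- V %*% t(R)
  V / sqrt(rowSums(V^2))
}

#' Parallel-transport the base frame of a chart to a vertex
#'
#' Transport along the minimizing geodesic is the rotation about the axis
#' `x0 x x` by the angle `arccos(x0 . x)`. At the antipode of the base
#' vertex, where the minimizing geodesic is not unique, a fixed two-leg
#' path through the base vertex's first neighbor is used so the chart stays
#' deterministic; the projection layer absorbs this choice.
#'
#' @param chart an [build_icosahedron()] chart.
#' @param to_vertex vertex index (1..12).
#' @return List with unit 3-vectors `e1`, `e2` forming, with the vertex, a
#'   right-handed orthonormal triple.
#' @export
transport_frame <- function(chart, to_vertex) {
  x0 <- chart$vertices[chart$base_index, ]
  x <- chart$vertices[to_vertex, ]
  e1 <- chart$base_frame$e1
  e2 <- chart$base_frame$e2
  d <- sum(x0 * x)
  if (d < -1 + 1e-10) {
    mid <- chart$vertices[chart$adjacency[[chart$base_index]][1], ]
    f <- .transport_leg(x0, mid, e1, e2)
    f <- .transport_leg(mid, x, f$e1, f$e2)
    return(f)
  }
  .transport_leg(x0, x, e1, e2)
}

.transport_leg <- function(from, to, e1, e2) {
  d <- max(-1, min(1, sum(from * to)))
  theta <- acos(d)
  if (theta < 1e-14) return(list(e1 = e1, e2 = e2))
  axis <- .cross3(from, to)
  R <- rotation_about_axis(axis, theta)
  list(e1 = as.numeric(R %*% e1), e2 = as.numeric(R %*% e2))
}

#' Build the icosahedral chart of the sphere
#'
#' Returns the 12 vertices of the regular icosahedron (vertex 1 at the north
#' pole by convention), the 5-neighbor adjacency, and a tangent frame at
#' every vertex. Two frame conventions are available; both are realisable
#' as parallel transport of the base frame along suitable path families, so
#' either is a valid choice of the transport paths the layers require:
#'
#' * `"neighbor"` (the network default): each vertex's `e1` points along
#'   the geodesic to its first (lowest-index) neighbor, `e2 = x x e1`. The
#'   five neighbor directions at an icosahedron vertex are exactly 2*pi/5
#'   apart (the vertex figure is a regular pentagon), so the polar kernel
#'   grid respects the local icosahedral geometry and the sampling pattern
#'   is the same at every vertex up to a global rotation.
#' * `"transport"`: the base vertex's frame (anchored at its first
#'   neighbor) is parallel-transported to every other vertex along the
#'   minimizing geodesic (see [transport_frame()]); the frames then carry
#'   arbitrary holonomy offsets relative to the local neighbor grids.
#'
#' @param base_index index in 1..12 of the base vertex anchoring the frames.
#' @param frames frame convention, `"neighbor"` or `"transport"`.
#' @return An object of class `bgcnn_chart`: list with `vertices` (12x3),
#'   `adjacency` (list of 5 neighbor indices each), `e1`, `e2` (12x3 frame
#'   matrices), `base_index`, `base_frame`, `frames`.
#' @export
build_icosahedron <- function(base_index = 1L,
                              frames = c("neighbor", "transport")) {
  stopifnot(base_index >= 1, base_index <= 12)
  frames <- match.arg(frames)
  V <- .icosahedron_vertices()
  D <- V %*% t(V)
  adjacency <- lapply(seq_len(12), function(i) {
    which(abs(D[i, ] - 1 / sqrt(5)) < 1e-8)
  })
  x0 <- V[base_index, ]
  nb1 <- V[adjacency[[base_index]][1], ]
  e1 <- .unit(log_map(x0, nb1))
  e2 <- .cross3(x0, e1)
  chart <- list(vertices = V, adjacency = adjacency,
                base_index = as.integer(base_index),
                base_frame = list(e1 = e1, e2 = e2), frames = frames)
  E1 <- matrix(0, 12, 3)
  E2 <- matrix(0, 12, 3)
  for (i in seq_len(12)) {
    if (frames == "neighbor") {
      v <- V[i, ]
      f1 <- .unit(log_map(v, V[adjacency[[i]][1], ]))
      f <- list(e1 = f1, e2 = .cross3(v, f1))
    } else {
      f <- transport_frame(chart, i)
    }
    E1[i, ] <- f$e1
    E2[i, ] <- f$e2
  }
  chart$e1 <- E1
  chart$e2 <- E2
  class(chart) <- "bgcnn_chart"
  chart
}

#' @export
print.bgcnn_chart <- function(x, ...) {
  cat("Icosahedral chart of S2: 12 vertices, 30 edges, base vertex",
      x$base_index, "\n")
  invisible(x)
}

#' Rotate one vertex's tangent frame about its own axis
#'
#' Used to re-anchor frames: the composed lift-correlate-project network is
#' exactly invariant under re-anchorings by multiples of 2*pi/5 (the grid's
#' cyclic symmetry) and only approximately invariant otherwise.
#'
#' @param chart a chart.
#' @param vertex vertex index.
#' @param angle rotation angle in radians (counter-clockwise seen from
#'   outside the sphere).
#' @return The chart with that frame rotated.
#' @export
rotate_vertex_frame <- function(chart, vertex, angle) {
  R <- rotation_about_axis(chart$vertices[vertex, ], angle)
  chart$e1[vertex, ] <- as.numeric(R %*% chart$e1[vertex, ])
  chart$e2[vertex, ] <- as.numeric(R %*% chart$e2[vertex, ])
  chart
}

#' Snap a chart's frames onto another chart's 5-fold grid
#'
#' Frames transported from different base vertices differ at each vertex by
#' an arbitrary holonomy angle. The discrete network is exactly invariant
#' only under re-anchorings by multiples of 2*pi/5, so to compare charts
#' with different base vertices each frame is realigned to the reference
#' frame rotated by the nearest multiple of 2*pi/5.
#'
#' @param chart chart whose frames are realigned.
#' @param reference chart supplying the reference frames (same embedding).
#' @return `chart` with every frame equal to the reference frame rotated by
#'   a multiple of 2*pi/5.
#' @export
realign_frames <- function(chart, reference) {
  step <- 2 * pi / 5
  for (i in seq_len(12)) {
    v <- chart$vertices[i, ]
    c_ <- sum(chart$e1[i, ] * reference$e1[i, ])
    s_ <- sum(chart$e1[i, ] * reference$e2[i, ])
    ang <- atan2(s_, c_)              # angle from reference e1 to chart e1
    k <- round(ang / step) %% 5
    R <- rotation_about_axis(v, k * step)
    chart$e1[i, ] <- as.numeric(R %*% reference$e1[i, ])
    chart$e2[i, ] <- as.numeric(R %*% reference$e2[i, ])
  }
  chart
}

#' Polar sampling grid of a tangent-plane kernel
#'
#' Offsets lie on `n_rays` rays at angles `2*pi*i/n_rays` (ray 0 along the
#' frame's `e1`), at radii `radius * j / n_samples_per_ray`, plus an
#' optional center sample. With the reference settings (radius 0.6, 5 rays,
#' 2 samples per ray, center included) the grid has 11 points.
#'
#' @param radius kernel support radius, arc length in radians; must be > 0.
#' @param n_rays number of rays (5 for the reference architecture).
#' @param n_samples_per_ray samples per ray.
#' @param include_center include the tangent-plane origin as a sample.
#' @return Object of class `bgcnn_grid`: list with `offsets` (K x 2 matrix
#'   of frame coordinates), `ray_of` (0-based ray index, NA for the center),
#'   `radial_of`, and the constructor arguments.
#' @export
build_kernel_grid <- function(radius = 0.6, n_rays = 5L,
                              n_samples_per_ray = 2L,
                              include_center = TRUE) {
  if (radius <= 0) stop("kernel radius must be positive")
  stopifnot(n_rays >= 1, n_samples_per_ray >= 1)
  offs <- list()
  ray_of <- integer(0)
  radial_of <- integer(0)
  if (include_center) {
    offs[[1]] <- c(0, 0)
    ray_of <- NA_integer_
    radial_of <- 0L
  }
  for (i in seq_len(n_rays) - 1L) {
    ang <- 2 * pi * i / n_rays
    for (j in seq_len(n_samples_per_ray)) {
      r <- radius * j / n_samples_per_ray
      offs[[length(offs) + 1L]] <- r * c(cos(ang), sin(ang))
      ray_of <- c(ray_of, i)
      radial_of <- c(radial_of, j)
    }
  }
  structure(list(offsets = do.call(rbind, offs),
                 ray_of = ray_of, radial_of = radial_of,
                 radius = radius, n_rays = as.integer(n_rays),
                 n_samples_per_ray = as.integer(n_samples_per_ray),
                 include_center = include_center),
            class = "bgcnn_grid")
}

#' @export
print.bgcnn_grid <- function(x, ...) {
  cat(sprintf("Polar kernel grid: %d offsets (%d rays x %d radii%s), radius %.3g rad\n",
              nrow(x$offsets), x$n_rays, x$n_samples_per_ray,
              if (x$include_center) " + center" else "", x$radius))
  invisible(x)
}

#' Kernel sample points for one vertex
#'
#' Maps each grid offset `p = (p1, p2)` through the exponential map at the
#' vertex, with the offset expressed in the vertex's transported frame:
#' `exp_map(x, p1 e1 + p2 e2)`.
#'
#' @param chart a chart.
#' @param vertex vertex index.
#' @param grid a [build_kernel_grid()] grid.
#' @return K x 3 matrix of unit vectors.
#' @export
sample_points_for_vertex <- function(chart, vertex, grid) {
  x <- chart$vertices[vertex, ]
  e1 <- chart$e1[vertex, ]
  e2 <- chart$e2[vertex, ]
  t(apply(grid$offsets, 1, function(p) exp_map(x, p[1] * e1 + p[2] * e2)))
}

#' All chart sample points, vertex-major
#'
#' @param chart a chart.
#' @param grid a grid.
#' @return (12*K) x 3 matrix; row `(v-1)*K + j` is offset `j` at vertex `v`.
#' @export
chart_sample_points <- function(chart, grid) {
  do.call(rbind, lapply(seq_len(12), function(v)
    sample_points_for_vertex(chart, v, grid)))
}
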