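#' The three network layers on the icosahedral chart
#'
#' Discrete forms of the lifting layer, the group-correlation layer over the
#' cyclic rotation group of each tangent plane, and the max projection that
#' removes the rotation (and with it, transport-path and base-point)
#' dependence. Features are numeric arrays: lifted features are indexed
#' `(vertex, rotation, channel)`, manifold features `(vertex, channel)`.
#'
#' @name gcnn-layers
NULL

# Permutations sigma_k of the grid offsets, one per discrete rotation
# k = 0..n_rays-1: the center is fixed and (ray i, radial s) is read from
# (ray (i-k) mod n_rays, radial s). Row k+1 holds sigma_k as 1-based indices.
grid_rotation_permutations <- function(grid) {
  K <- nrow(grid$offsets)
  nr <- grid$n_rays
  idx_of <- function(ray, radial) {
    w <- which(!is.na(grid$ray_of) & grid$ray_of == ray &
                 grid$radial_of == radial)
    if (length(w) != 1)
      stop("kernel grid lacks full cyclic symmetry: missing (ray, radial) sample")
    w
  }
  P <- matrix(0L, nr, K)
  for (k in seq_len(nr) - 1L) {
    for (j in seq_len(K)) {
      if (is.na(grid$ray_of[j])) {
        P[k + 1L, j] <- j
      } else {
        P[k + 1L, j] <- idx_of((grid$ray_of[j] - k) %% nr, grid$radial_of[j])
      }
    }
  }
  P
}

#' Create a lifting kernel
#'
#' @param weights array `(in_channel, out_channel, grid_offset)`.
#' @param bias numeric vector, one per out channel.
#' @return Object of class `bgcnn_lift_kernel`.
#' @export
lift_kernel <- function(weights, bias) {
  stopifnot(length(dim(weights)) == 3, length(bias) == dim(weights)[2],
            all(is.finite(weights)), all(is.finite(bias)))
  structure(list(weights = weights, bias = as.numeric(bias)),
            class = "bgcnn_lift_kernel")
}

#' Create a group-correlation kernel
#'
#' @param weights array `(in_channel, out_channel, rotation)`.
#' @param bias numeric vector, one per out channel.
#' @return Object of class `bgcnn_group_kernel`.
#' @export
group_kernel <- function(weights, bias) {
  stopifnot(length(dim(weights)) == 3, length(bias) == dim(weights)[2],
            all(is.finite(weights)), all(is.finite(bias)))
  structure(list(weights = weights, bias = as.numeric(bias)),
            class = "bgcnn_group_kernel")
}

#' Lifting layer
#'
#' Correlates the resampled signal at each vertex with the tangent-plane
#' kernel at each of the `n_rays` discrete rotations. The rotated kernel is
#' realised by the cyclic offset permutation: output
#' `F[v, k, c_out] = sum_{c_in, j} w[c_in, c_out, j] * x[v, c_in, sigma_k(j)]
#' + b[c_out]`, the discretisation of the tangent-plane correlation integral
#' by the substitution `v = R_k p_j`.
#'
#' @param sampled_values array `(12, in_channels, K)` of signal values at the
#'   vertex sample points (see [sample_points_for_vertex()]).
#' @param kernel a [lift_kernel()].
#' @param grid the [build_kernel_grid()] the values were sampled on; must
#'   have full cyclic symmetry.
#' @return Lifted feature array `(12, n_rays, out_channels)`.
#' @export
lift_forward <- function(sampled_values, kernel, grid) {
  dW <- dim(kernel$weights)
  dS <- dim(sampled_values)
  if (length(dS) != 3 || dS[2] != dW[1] || dS[3] != dW[3])
    stop("sampled_values must be (vertices, in_channels, grid_offsets) matching the kernel")
  P <- grid_rotation_permutations(grid)
  nr <- nrow(P)
  nV <- dS[1]
  out <- array(0, dim = c(nV, nr, dW[2]))
  for (k in seq_len(nr)) {
    for (co in seq_len(dW[2])) {
      acc <- matrix(0, nV, 1)
      for (ci in seq_len(dW[1])) {
        acc <- acc + sampled_values[, ci, P[k, ], drop = FALSE][, 1, ] %*%
          kernel$weights[ci, co, ]
      }
      out[, k, co] <- acc + kernel$bias[co]
    }
  }
  out
}

#' Group-correlation layer
#'
#' Correlation over the cyclic rotation group of each tangent plane; the
#' Haar integral becomes the uniform sum over the discrete rotations:
#' `out[v, s, c_out] = sum_{c_in, r} F[v, r, c_in] *
#' w[c_in, c_out, (r-s) mod n] + b[c_out]`. The same kernel indices apply at
#' every vertex because conjugating by the transport isometry preserves the
#' rotation angle on consistently oriented tangent planes.
#'
#' @param F lifted feature array `(vertices, rotations, in_channels)`.
#' @param kernel a [group_kernel()] with matching channel and rotation dims.
#' @return Lifted feature array `(vertices, rotations, out_channels)`.
#' @export
group_correlate <- function(F, kernel) {
  dW <- dim(kernel$weights)
  dF <- dim(F)
  if (length(dF) != 3 || dF[3] != dW[1])
    stop("input channels do not match the group kernel")
  if (dF[2] != dW[3])
    stop("rotation count of the feature and kernel must agree")
  nr <- dF[2]
  out <- array(0, dim = c(dF[1], nr, dW[2]))
  for (s in seq_len(nr) - 1L) {
    for (co in seq_len(dW[2])) {
      acc <- 0
      for (r in seq_len(nr) - 1L) {
        for (ci in seq_len(dW[1])) {
          acc <- acc + F[, r + 1L, ci] * kernel$weights[ci, co, ((r - s) %% nr) + 1L]
        }
      }
      out[, s + 1L, co] <- acc + kernel$bias[co]
    }
  }
  out
}

#' Max projection layer
#'
#' Collapses the rotation axis by a per-vertex, per-channel maximum,
#' producing manifold features invariant to cyclic shifts of the rotation
#' axis — the discrete counterpart of maximising over the tangent rotation
#' group, which removes transport-path and base-point dependence.
#'
#' @param F lifted feature array `(vertices, rotations, channels)`.
#' @return Manifold feature matrix `(vertices, channels)`.
#' @export
project_max <- function(F) {
  apply(F, c(1, 3), max)
}

#' Rectified linear unit
#'
#' @param x numeric array.
#' @return `pmax(x, 0)` with the shape preserved.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}
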