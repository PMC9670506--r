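#' Spherical signal
#'
#' One voxel's (or one synthetic sample's) directional measurements: unit
#' gradient directions paired with values, possibly multi-channel.
#'
#' @param directions N x 3 matrix of unit vectors.
#' @param values numeric vector of length N, or N x Nc matrix for Nc
#'   channels.
#' @return Object of class `bgcnn_signal` with `directions` (N x 3) and
#'   `values` (N x Nc matrix).
#' @export
spherical_signal <- function(directions, values) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("directions must be unit vectors")
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) != nrow(directions))
    stop("one value row per direction is required")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(directions = directions, values = values),
            class = "bgcnn_signal")
}

#' @export
print.bgcnn_signal <- function(x, ...) {
  cat(sprintf("Spherical signal: %d directions, %d channel(s)\n",
              nrow(x$directions), ncol(x$values)))
  invisible(x)
}

#' Watson interpolation weights
#'
#' Row-normalised weight matrix for interpolating a directional signal from
#' its acquisition directions onto arbitrary query points. The unnormalised
#' weight of data direction `g` at query `q` is `exp(kappa * (q.g)^2)` — the
#' antipodally symmetric Watson kernel, matching the symmetry of
#' diffusion-weighted measurements. Row normalisation makes the weights a
#' partition of unity, so the Watson normalising constant cancels.
#'
#' @param directions N x 3 matrix of unit data directions.
#' @param queries M x 3 matrix of unit query points.
#' @param kappa concentration parameter, > 0.
#' @return M x N matrix with nonnegative rows summing to 1.
#' @export
watson_weight_matrix <- function(directions, queries, kappa) {
  if (kappa <= 0) stop("kappa must be positive")
  directions <- as.matrix(directions)
  queries <- as.matrix(queries)
  stopifnot(ncol(directions) == 3, ncol(queries) == 3,
            nrow(directions) >= 1, nrow(queries) >= 1)
  C <- tcrossprod(queries, directions)       # M x N cosines
  E <- kappa * C^2
  E <- E - apply(E, 1, max)                  # guard overflow for large kappa
  W <- exp(E)
  W / rowSums(W)
}

#' Resample a spherical signal at query points
#'
#' Applies a precomputed Watson weight matrix channel-wise: the interpolated
#' values are `weights %*% values`, a linear map of the signal.
#'
#' @param signal a [spherical_signal()] (or an N x Nc value matrix).
#' @param weights M x N weight matrix from [watson_weight_matrix()] computed
#'   from the signal's directions.
#' @return M x Nc matrix of interpolated values.
#' @export
resample_signal <- function(signal, weights) {
  values <- if (inherits(signal, "bgcnn_signal")) signal$values
            else as.matrix(signal)
  if (ncol(weights) != nrow(values))
    stop("weight matrix columns must match the number of directions")
  weights %*% values
}
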