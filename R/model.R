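#' Classifier configuration
#'
#' Settings of the lift-ReLU-conv-ReLU-projection-FC-softmax voxel
#' classifier. The reference architecture uses 1 lift channel, 5 conv
#' channels, kernel radius 0.6 rad, 5 rays with 2 samples per ray (plus the
#' center: an 11-point grid), and a Watson concentration suited to the
#' acquisition (10 for the tissue tasks, 5 for the synthetic task).
#'
#' @param n_input_channels number of signal channels Nc.
#' @param n_lift_channels lift-layer output channels.
#' @param n_conv_channels group-correlation output channels.
#' @param n_classes classes of the softmax head.
#' @param kernel_radius tangent kernel radius (radians of arc).
#' @param n_rays rays of the polar grid (= discrete rotation count).
#' @param n_samples_per_ray samples per ray.
#' @param kappa Watson concentration for input interpolation.
#' @param seed integer seed for weight initialization.
#' @return A `bgcnn_classifier_config` list.
#' @export
classifier_config <- function(n_input_channels = 1L, n_lift_channels = 1L,
                              n_conv_channels = 5L, n_classes = 2L,
                              kernel_radius = 0.6, n_rays = 5L,
                              n_samples_per_ray = 2L, kappa = 5,
                              seed = 1L) {
  cfg <- list(n_input_channels = as.integer(n_input_channels),
              n_lift_channels = as.integer(n_lift_channels),
              n_conv_channels = as.integer(n_conv_channels),
              n_classes = as.integer(n_classes),
              kernel_radius = kernel_radius, n_rays = as.integer(n_rays),
              n_samples_per_ray = as.integer(n_samples_per_ray),
              kappa = kappa, seed = as.integer(seed))
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stop("all classifier configuration fields must be positive scalars")
  if (cfg$n_classes < 2) stop("at least 2 classes are required")
  structure(cfg, class = "bgcnn_classifier_config")
}

.he_uniform <- function(n, fan_in) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

#' Build the spherical voxel classifier
#'
#' Assembles the lift-ReLU-conv-ReLU-projection-FC-softmax network over the
#' icosahedral chart: one lifting kernel bank (`Nc -> n_lift` over the grid
#' offsets), one group kernel bank (`n_lift -> n_conv` over the rotations),
#' and a single dense layer from the flattened `12 * n_conv` manifold
#' features (vertex-major, channel fastest) to the class logits. Weights
#' are He-style fan-in-scaled uniform draws from the config seed; biases
#' start at zero.
#'
#' @param config a [classifier_config()].
#' @param chart optionally a prebuilt [build_icosahedron()] chart.
#' @return Object of class `bgcnn_classifier`.
#' @export
build_classifier <- function(config, chart = NULL) {
  if (!inherits(config, "bgcnn_classifier_config"))
    config <- do.call(classifier_config, as.list(config))
  if (is.null(chart)) chart <- build_icosahedron()
  grid <- build_kernel_grid(config$kernel_radius, config$n_rays,
                            config$n_samples_per_ray, include_center = TRUE)
  K <- nrow(grid$offsets)
  nc <- config$n_input_channels; nl <- config$n_lift_channels
  ng <- config$n_conv_channels; ncls <- config$n_classes
  nr <- config$n_rays
  params <- withr::with_seed(config$seed, {
    list(
      lift_w = array(.he_uniform(nc * nl * K, nc * K), dim = c(nc, nl, K)),
      lift_b = rep(0, nl),
      conv_w = array(.he_uniform(nl * ng * nr, nl * nr), dim = c(nl, ng, nr)),
      conv_b = rep(0, ng),
      fc_w = matrix(.he_uniform(12 * ng * ncls, 12 * ng), 12 * ng, ncls),
      fc_b = rep(0, ncls)
    )
  })
  structure(list(config = config, chart = chart, grid = grid,
                 perm = grid_rotation_permutations(grid),
                 query = chart_sample_points(chart, grid),
                 params = params),
            class = "bgcnn_classifier")
}

#' @export
print.bgcnn_classifier <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Spherical geodesic CNN classifier: %d->%d lift, %d conv, %d classes (%d parameters)\n",
    cfg$n_input_channels, cfg$n_lift_channels, cfg$n_conv_channels,
    cfg$n_classes, count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar, biases included. For the reference
#' settings (1 input channel, 1 lift, 5 conv channels) the closed form is
#' `11 + 1 + 25 + 5 + 12*5*n_classes + n_classes`, i.e. 164 / 286 / 408
#' parameters for 2 / 4 / 6 classes.
#'
#' @param model a fitted or freshly built model.
#' @return Integer count.
#' @export
count_parameters <- function(model) UseMethod("count_parameters")

#' @export
count_parameters.bgcnn_classifier <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
count_parameters.bgcnn_mlp <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Fully connected baseline configuration
#'
#' @param layer_widths integer vector: input width first, class count last
#'   (e.g. `c(90, 50, 30, 2)`).
#' @param hidden_norm apply per-unit scale-and-shift normalisation (layer
#'   normalisation with learnable gain and shift) on the hidden layers;
#'   adds `2 * width` parameters per hidden layer, which reproduces the
#'   printed baseline parameter totals.
#' @param kappa Watson concentration used when interpolating signals onto
#'   the baseline's fixed input directions.
#' @param seed integer seed for weight initialization.
#' @return A `bgcnn_mlp_config` list.
#' @export
mlp_config <- function(layer_widths, hidden_norm = TRUE, kappa = 5,
                       seed = 1L) {
  layer_widths <- as.integer(layer_widths)
  if (length(layer_widths) < 2 || any(layer_widths <= 0))
    stop("layer_widths must be >= 2 positive widths")
  stopifnot(kappa > 0)
  structure(list(layer_widths = layer_widths,
                 hidden_norm = isTRUE(hidden_norm), kappa = kappa,
                 seed = as.integer(seed)),
            class = "bgcnn_mlp_config")
}

#' Build the fully connected baseline
#'
#' A plain dense stack with ReLU between layers and softmax output,
#' consuming the per-direction values interpolated at the fixed acquisition
#' directions (no geometric layers).
#'
#' @param config an [mlp_config()].
#' @return Object of class `bgcnn_mlp`.
#' @export
build_mlp_baseline <- function(config) {
  if (!inherits(config, "bgcnn_mlp_config"))
    config <- do.call(mlp_config, as.list(config))
  w <- config$layer_widths
  L <- length(w) - 1L
  params <- withr::with_seed(config$seed, {
    p <- list()
    for (l in seq_len(L)) {
      p[[paste0("W", l)]] <- matrix(.he_uniform(w[l] * w[l + 1], w[l]),
                                    w[l], w[l + 1])
      p[[paste0("b", l)]] <- rep(0, w[l + 1])
      if (config$hidden_norm && l < L) {
        p[[paste0("g", l)]] <- rep(1, w[l + 1])
        p[[paste0("s", l)]] <- rep(0, w[l + 1])
      }
    }
    p
  })
  structure(list(config = config, params = params), class = "bgcnn_mlp")
}

#' @export
print.bgcnn_mlp <- function(x, ...) {
  cat(sprintf("Dense baseline FC(%s)%s (%d parameters)\n",
              paste(x$config$layer_widths, collapse = ")-FC("),
              if (x$config$hidden_norm) " with hidden normalisation" else "",
              count_parameters(x)))
  invisible(x)
}

#' Class probabilities for spherical signals
#'
#' Resamples the signal onto the chart sample points with the model's
#' Watson configuration, then runs lift -> ReLU -> group correlation ->
#' ReLU -> max projection -> dense -> softmax.
#'
#' @param object a [build_classifier()] model.
#' @param newdata a [spherical_signal()], a list of them, or a dataset
#'   tibble from [generate_dataset()].
#' @param type `"prob"` for class probabilities, `"class"` for hard labels.
#' @param ... unused.
#' @return Matrix `(n_samples, n_classes)` of probabilities, or an integer
#'   vector of predicted labels (0-based, matching dataset labels).
#' @export
predict.bgcnn_classifier <- function(object, newdata, type = c("prob", "class"),
                                     ...) {
  type <- match.arg(type)
  X <- prepare_classifier_inputs(object, newdata)
  p <- .cls_forward(object$params, X, object$perm,
                    dims = .cls_dims(object))$p
  if (type == "class") return(max.col(p, ties.method = "first") - 1L)
  p
}

#' @rdname predict.bgcnn_classifier
#' @export
predict.bgcnn_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else prepare_mlp_inputs(object, newdata)
  p <- .mlp_forward(object$params, X, object$config)$p
  if (type == "class") return(max.col(p, ties.method = "first") - 1L)
  p
}

#' Serialize a model to a versioned JSON checkpoint
#'
#' Stores weights, configuration and the chart convention identifier so a
#' model reloads bit-exactly (doubles are written in full precision).
#'
#' @param model a classifier or baseline model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  kind <- if (inherits(model, "bgcnn_classifier")) "classifier" else "mlp"
  obj <- list(
    format = "bgcnn-checkpoint", version = 1L, kind = kind,
    chart_convention = if (kind == "classifier") "icosahedron-goldenratio-north-v1" else NULL,
    config = unclass(model$config),
    # doubles as %.17g strings: 17 significant digits round-trip IEEE-754
    # exactly, which plain JSON number emission does not guarantee
    params = lapply(model$params, function(p)
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = sprintf("%.17g", as.numeric(p))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path checkpoint file written by [write_checkpoint()].
#' @return The restored model.
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bgcnn-checkpoint"))
    stop("not a bgcnn checkpoint: ", path)
  restore <- function(p) {
    d <- as.integer(p$dim)
    if (length(d) == 1) as.numeric(p$data) else array(as.numeric(p$data), dim = d)
  }
  if (obj$kind == "classifier") {
    cfg <- do.call(classifier_config, obj$config)
    model <- build_classifier(cfg)
  } else {
    cfg <- do.call(mlp_config, obj$config)
    model <- build_mlp_baseline(cfg)
  }
  stopifnot(identical(sort(names(model$params)), sort(names(obj$params))))
  for (nm in names(model$params)) {
    p <- restore(obj$params[[nm]])
    if (is.matrix(model$params[[nm]])) p <- matrix(p, nrow(model$params[[nm]]))
    model$params[[nm]] <- p
  }
  model
}
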