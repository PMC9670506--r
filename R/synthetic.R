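#' Synthetic rotation-classification benchmark
#'
#' Generates the rotation dataset used to verify rotational invariance
#' end-to-end without any scan data: 90 directions sampled uniformly on a
#' hemisphere are shared by all classes; each class draws 90 function
#' values from the same standard Gaussian (so classes are indistinguishable
#' by value statistics); every sample of a class is an independently,
#' Haar-uniformly rotated copy of that class's spherical function. The task
#' is to recognise the class from an arbitrary rotation of its function.
#'
#' @name synthetic-data
NULL

#' Synthetic dataset specification
#'
#' @param n_classes number of classes (>= 2).
#' @param n_directions directions per sample.
#' @param n_train_per_class training samples per class.
#' @param n_test_per_class test samples per class.
#' @param value_sd standard deviation of the Gaussian function values.
#' @param seed integer seed: the dataset is a pure function of this spec.
#' @return A `bgcnn_synth_spec` list.
#' @export
synth_spec <- function(n_classes = 2L, n_directions = 90L,
                       n_train_per_class = 50L, n_test_per_class = 1000L,
                       value_sd = 1, seed = 1L) {
  stopifnot(n_classes >= 2, n_directions >= 1, n_train_per_class >= 1,
            n_test_per_class >= 1, value_sd > 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_directions = as.integer(n_directions),
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 value_sd = value_sd, seed = as.integer(seed)),
            class = "bgcnn_synth_spec")
}

#' Uniform directions on the upper hemisphere
#'
#' Area-uniform draws with nonnegative z: z ~ U(0, 1), azimuth ~ U(0, 2*pi).
#'
#' @param n number of directions.
#' @param seed integer seed.
#' @return n x 3 matrix of unit vectors with `z >= 0`.
#' @export
sample_hemisphere_directions <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    z <- stats::runif(n)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    unname(cbind(r * cos(phi), r * sin(phi), z))
  })
}

#' Per-class prototype value vectors
#'
#' One i.i.d. Gaussian value vector per class, all drawn from the same
#' distribution so classes share the same scale and differ only in the
#' arrangement of values over the shared directions. Note that with i.i.d.
#' draws the per-class sample means still differ by sampling noise
#' (sd about `value_sd / sqrt(n_directions)`), a weak rotation-invariant
#' cue that flexible non-geometric learners can pick up.
#'
#' @param spec a [synth_spec()].
#' @return `n_classes` x `n_directions` matrix.
#' @export
make_class_prototypes <- function(spec) {
  stopifnot(inherits(spec, "bgcnn_synth_spec"))
  withr::with_seed(spec$seed + 1L, {
    matrix(stats::rnorm(spec$n_classes * spec$n_directions, 0, spec$value_sd),
           spec$n_classes, spec$n_directions, byrow = TRUE)
  })
}

#' Haar-uniform random rotation
#'
#' Draws a rotation uniformly from SO(3) via a normalised Gaussian
#' quaternion. Consumes the current RNG stream (seed it with `set.seed()`
#' or `withr::with_seed()` for reproducibility).
#'
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate the rotation-classification dataset
#'
#' For every class, draws `n_train_per_class + n_test_per_class`
#' independent Haar rotations; each sample pairs the rotated base
#' directions with the class's fixed prototype values. Train and test are
#' disjoint by independence of the rotations.
#'
#' @param spec a [synth_spec()].
#' @return Tibble with columns `sample_id`, `split` ("train"/"test"),
#'   `label` (0-based), and list columns `rotation` (3x3), `directions`
#'   (n x 3), `values` (n). Attributes `base_directions`, `prototypes`, and
#'   `spec` record the generating quantities.
#' @export
generate_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "bgcnn_synth_spec"))
  base <- sample_hemisphere_directions(spec$n_directions, spec$seed)
  proto <- make_class_prototypes(spec)
  per_class <- spec$n_train_per_class + spec$n_test_per_class
  rows <- withr::with_seed(spec$seed + 2L, {
    out <- vector("list", spec$n_classes * per_class)
    i <- 0L
    for (cls in seq_len(spec$n_classes) - 1L) {
      for (j in seq_len(per_class)) {
        R <- random_rotation()
        i <- i + 1L
        out[[i]] <- list(
          split = if (j <= spec$n_train_per_class) "train" else "test",
          label = cls, rotation = R,
          directions = base %*% t(R),
          values = proto[cls + 1L, ])
      }
    }
    out
  })
  ds <- tibble::tibble(
    sample_id = seq_along(rows),
    split = vapply(rows, `[[`, character(1), "split"),
    label = vapply(rows, `[[`, integer(1), "label"),
    rotation = lapply(rows, `[[`, "rotation"),
    directions = lapply(rows, `[[`, "directions"),
    values = lapply(rows, `[[`, "values")
  )
  attr(ds, "base_directions") <- base
  attr(ds, "prototypes") <- proto
  attr(ds, "spec") <- spec
  ds
}

#' Export a dataset to plain-text files
#'
#' Writes a two-file pair: `<prefix>_signals.csv`, one row per
#' (sample, direction) with the unit direction and value, and
#' `<prefix>_labels.csv`, one row per sample with split and label. The
#' schema round-trips through [read_synth_dataset()].
#'
#' @param dataset a [generate_dataset()] tibble.
#' @param prefix output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_synth_dataset <- function(dataset, prefix) {
  sig <- do.call(rbind, lapply(seq_len(nrow(dataset)), function(i) {
    d <- dataset$directions[[i]]
    data.frame(sample_id = dataset$sample_id[i],
               direction_index = seq_len(nrow(d)),
               gx = d[, 1], gy = d[, 2], gz = d[, 3],
               value = dataset$values[[i]])
  }))
  lab <- data.frame(sample_id = dataset$sample_id, split = dataset$split,
                    label = dataset$label)
  fs <- paste0(prefix, c("_signals.csv", "_labels.csv"))
  utils::write.csv(sig, fs[1], row.names = FALSE)
  utils::write.csv(lab, fs[2], row.names = FALSE)
  invisible(fs)
}

#' Import a dataset written by [write_synth_dataset()]
#'
#' @param prefix the path prefix used at export.
#' @return A dataset tibble (without the generator attributes).
#' @export
read_synth_dataset <- function(prefix) {
  sig <- utils::read.csv(paste0(prefix, "_signals.csv"))
  lab <- utils::read.csv(paste0(prefix, "_labels.csv"))
  ids <- lab$sample_id
  directions <- lapply(ids, function(id) {
    s <- sig[sig$sample_id == id, ]
    s <- s[order(s$direction_index), ]
    as.matrix(s[, c("gx", "gy", "gz")])
  })
  values <- lapply(ids, function(id) {
    s <- sig[sig$sample_id == id, ]
    s$value[order(s$direction_index)]
  })
  tibble::tibble(sample_id = ids, split = lab$split,
                 label = as.integer(lab$label),
                 directions = directions, values = values)
}
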