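#' Diffusion-weighted imaging plumbing
#'
#' NIfTI volume handling, FSL-style bval/bvec gradient tables, shell
#' extraction, b0 normalisation, and per-class voxel subsampling for
#' single-shell voxel classification.
#'
#' @name dwi-io
NULL

#' Read FSL-style gradient tables
#'
#' `bval` is a whitespace-separated row of b-values (s/mm^2); `bvec` holds
#' the unit gradient directions either as 3 rows x N columns (FSL dialect)
#' or N rows x 3 columns; the orientation is auto-detected and a 3x3 table
#' is rejected as ambiguous. The zero vector is allowed for b0 volumes.
#'
#' @param bval_path,bvec_path file paths.
#' @return Object of class `bgcnn_gradients`: list with `bvals` (length N)
#'   and `bvecs` (N x 3).
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  m <- as.matrix(utils::read.table(bvec_path))
  if (nrow(m) == 3 && ncol(m) == 3)
    stop("3x3 bvec table is ambiguous (cannot tell rows from columns)")
  if (nrow(m) == 3) m <- t(m)
  if (ncol(m) != 3) stop("bvec table must be 3xN or Nx3")
  if (nrow(m) != length(bvals))
    stop("bval/bvec length mismatch: ", length(bvals), " vs ", nrow(m))
  nz <- sqrt(rowSums(m^2)) > 1e-8
  norms <- sqrt(rowSums(m[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-3))
    stop("nonzero gradient directions must be unit vectors")
  dimnames(m) <- NULL
  structure(list(bvals = bvals, bvecs = m), class = "bgcnn_gradients")
}

#' Load a 4D DWI volume with its gradient table
#'
#' @param image_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL gradient table files.
#' @return List with `image` (the `niftiImage`), `data` (4D array),
#'   `gradients` ([read_gradient_table()]), and `affine`.
#' @export
load_dwi <- function(image_path, bval_path, bvec_path) {
  for (p in c(image_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("expected a 4D DWI image, got ", length(dim(arr)), "D")
  grad <- read_gradient_table(bval_path, bvec_path)
  if (dim(arr)[4] != length(grad$bvals))
    stop("volume count (", dim(arr)[4], ") does not match gradient table (",
         length(grad$bvals), ")")
  list(image = img, data = arr, gradients = grad,
       affine = RNifti::xform(img))
}

#' Extract a single shell and the b0 volumes
#'
#' Partitions the 4D series into b0 volumes (`b <= b0_threshold`), the
#' target shell (`|b - b_target| <= tolerance`), and rejected volumes.
#'
#' @param data 4D array.
#' @param gradients a [read_gradient_table()] object.
#' @param b_target shell b-value (s/mm^2).
#' @param tolerance shell matching tolerance (s/mm^2).
#' @param b0_threshold maximum b-value treated as unweighted.
#' @return List with `shell` (4D array of shell volumes), `directions`
#'   (n_shell x 3), `b0` (4D array of b0 volumes), and the three index
#'   vectors `shell_idx`, `b0_idx`, `rejected_idx`.
#' @export
extract_shell <- function(data, gradients, b_target, tolerance = 50,
                          b0_threshold = 50) {
  b <- gradients$bvals
  b0_idx <- which(b <= b0_threshold)
  shell_idx <- setdiff(which(abs(b - b_target) <= tolerance), b0_idx)
  if (length(shell_idx) == 0) stop("no volumes on shell b=", b_target)
  if (length(b0_idx) == 0) stop("no b0 volumes found")
  list(shell = data[, , , shell_idx, drop = FALSE],
       directions = gradients$bvecs[shell_idx, , drop = FALSE],
       b0 = data[, , , b0_idx, drop = FALSE],
       shell_idx = shell_idx, b0_idx = b0_idx,
       rejected_idx = setdiff(seq_along(b), c(shell_idx, b0_idx)))
}

#' Normalise shell volumes by the voxel-wise mean b0
#'
#' Divides every shell volume by the per-voxel average of the b0 volumes,
#' removing the arbitrary signal scale. Voxels whose mean b0 is not
#' positive are masked out (set to `NA`) and reported.
#'
#' @param shell 4D array of shell volumes.
#' @param b0 4D array of b0 volumes (same spatial grid).
#' @return List with `normalized` (4D array), `mask` (3D logical, TRUE
#'   where valid), and `n_masked`.
#' @export
normalize_by_b0 <- function(shell, b0) {
  stopifnot(length(dim(shell)) == 4, length(dim(b0)) == 4,
            all(dim(shell)[1:3] == dim(b0)[1:3]))
  mb0 <- apply(b0, c(1, 2, 3), mean)
  if (all(mb0 == 0)) stop("all-zero b0 volume")
  mask <- mb0 > 0
  denom <- mb0
  denom[!mask] <- 1
  out <- sweep(shell, c(1, 2, 3), denom, "/")
  out[array(!mask, dim = dim(shell))] <- NA_real_
  list(normalized = out, mask = mask, n_masked = sum(!mask))
}

#' Per-class voxel subsampling
#'
#' Seeded uniform sampling without replacement of a requested number of
#' voxels from each class, used to probe how much labelled data the
#' classifier needs.
#'
#' @param labels integer vector or 3D array of class labels.
#' @param per_class_counts named or ordered vector: requested count per
#'   class (names are class values; unnamed vectors map onto the sorted
#'   unique labels).
#' @param seed integer seed.
#' @return Named list of integer index vectors (into `labels` as a vector).
#' @export
subsample_training_voxels <- function(labels, per_class_counts, seed = 1L) {
  lab <- as.integer(labels)
  classes <- if (!is.null(names(per_class_counts)))
    as.integer(names(per_class_counts)) else sort(unique(lab))
  if (length(classes) != length(per_class_counts))
    stop("one count per class is required")
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (i in seq_along(classes)) {
      idx <- which(lab == classes[i])
      k <- per_class_counts[i]
      if (k > length(idx))
        stop("class ", classes[i], " has only ", length(idx),
             " voxels, cannot sample ", k)
      out[[as.character(classes[i])]] <- sort(sample(idx, k))
    }
    out
  })
}

#' Extract labelled per-voxel spherical signals
#'
#' @param shell 4D array of shell volumes.
#' @param directions n x 3 shell directions.
#' @param labels 3D array of integer labels; voxels with label
#'   `background` are skipped.
#' @param voxel_idx optional vector of linear voxel indices to keep.
#' @param background label value treated as unlabelled.
#' @return List with `signals` (list of [spherical_signal()]), `labels`
#'   (0-based consecutive classes), `classes` (original label values), and
#'   `voxel_idx`.
#' @export
labeled_voxel_set <- function(shell, directions, labels, voxel_idx = NULL,
                              background = 0L) {
  stopifnot(all(dim(labels) == dim(shell)[1:3]))
  lab <- as.integer(labels)
  if (is.null(voxel_idx)) voxel_idx <- which(lab != background)
  voxel_idx <- voxel_idx[lab[voxel_idx] != background]
  nvol <- dim(shell)[4]
  flat <- matrix(shell, ncol = nvol)          # voxel x volume
  classes <- sort(unique(lab[voxel_idx]))
  signals <- lapply(voxel_idx, function(v)
    spherical_signal(directions, flat[v, ]))
  list(signals = signals,
       labels = match(lab[voxel_idx], classes) - 1L,
       classes = classes, voxel_idx = voxel_idx)
}

#' Write a tiny synthetic DWI fixture scan
#'
#' Generates a synthetic 4D NIfTI scan with FSL tables and a co-registered
#' label volume for offline testing of every IO path: two tissue blocks
#' with distinct diffusion-tensor profiles (anisotropic along z vs.
#' isotropic), `n_b0` unweighted volumes, Rician-free Gaussian noise. The
#' data are synthetic stand-ins, not measurements.
#'
#' @param dir output directory.
#' @param dim_xyz spatial dimensions.
#' @param n_dirs gradient directions on the shell.
#' @param n_b0 number of b0 volumes.
#' @param bvalue shell b-value (s/mm^2).
#' @param noise_sd Gaussian noise standard deviation (signal scale 1).
#' @param seed integer seed.
#' @return Named list of the four file paths (`dwi`, `bval`, `bvec`,
#'   `labels`).
#' @export
write_dwi_fixture <- function(dir, dim_xyz = c(6, 6, 6), n_dirs = 12L,
                              n_b0 = 2L, bvalue = 1000, noise_sd = 0.02,
                              seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- sample_hemisphere_directions(n_dirs, seed)
  nx <- dim_xyz[1]; ny <- dim_xyz[2]; nz <- dim_xyz[3]
  labels <- array(0L, dim = dim_xyz)
  labels[seq_len(floor(nx / 2)), , ] <- 1L    # anisotropic tissue
  labels[(floor(nx / 2) + 1):nx, , ] <- 2L    # isotropic tissue
  # tensor profiles: signal = exp(-b g' D g), b in ms/um^2 scale
  bd <- bvalue / 1000
  D1 <- diag(c(0.2, 0.2, 1.7))                # strongly anisotropic
  D2 <- diag(c(0.7, 0.7, 0.7))                # isotropic
  att <- function(D) exp(-bd * rowSums((dirs %*% D) * dirs))
  sig <- rbind(att(D1), att(D2))              # 2 x n_dirs
  nvol <- n_b0 + n_dirs
  data <- withr::with_seed(as.integer(seed) + 1L, {
    a <- array(0, dim = c(dim_xyz, nvol))
    noise <- array(stats::rnorm(prod(dim_xyz) * nvol, 0, noise_sd),
                   dim = c(dim_xyz, nvol))
    for (v in seq_len(n_b0)) a[, , , v] <- 1
    for (d in seq_len(n_dirs)) {
      vol <- array(0, dim = dim_xyz)
      vol[labels == 1L] <- sig[1, d]
      vol[labels == 2L] <- sig[2, d]
      a[, , , n_b0 + d] <- vol
    }
    pmax(a + noise, 0)
  })
  paths <- list(dwi = file.path(dir, "fixture_dwi.nii"),
                bval = file.path(dir, "fixture.bval"),
                bvec = file.path(dir, "fixture.bvec"),
                labels = file.path(dir, "fixture_labels.nii"))
  RNifti::writeNifti(RNifti::asNifti(data, datatype = "double"), paths$dwi)
  writeLines(paste(c(rep(0, n_b0), rep(bvalue, n_dirs)), collapse = " "),
             paths$bval)
  bv <- rbind(matrix(0, n_b0, 3), dirs)
  # FSL dialect: 3 lines (x, y, z), one column per volume
  write(as.vector(bv), file = paths$bvec, ncolumns = nrow(bv))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(labels), dim = dim_xyz),
                                     datatype = "double"), paths$labels)
  invisible(paths)
}
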