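#' Reproducible experiment drivers
#'
#' High-level entry points tying the modules together; also backs the
#' `bgcnn` command-line script. Every run can write a manifest (config,
#' seeds, package version) sufficient to replay it exactly.
#'
#' @name experiments
NULL

.write_manifest <- function(output_dir, config) {
  manifest <- list(
    package = "bgcnn",
    version = as.character(utils::packageVersion("bgcnn")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Run the synthetic rotation-classification experiment
#'
#' Generates the rotation dataset, trains the spherical classifier and/or
#' the dense baseline, and reports test accuracy with parameter counts.
#' Defaults follow the synthetic benchmark settings: Watson kappa 5,
#' learning rate 0.005, 200 epochs, cross-entropy (focal gamma 0).
#'
#' @param n_classes number of classes (2, 4, or 6 in the benchmark).
#' @param model `"gcnn"`, `"baseline"`, or `"both"`.
#' @param seed master seed: seeds the dataset, weight init, and shuffling.
#' @param epochs,learning_rate,batch_size training settings.
#' @param kappa Watson concentration.
#' @param n_restarts number of seeded initializations to train; the run
#'   with the lowest final training loss is kept. The tiny classifier is
#'   sensitive to initialization (occasional runs settle in poor optima);
#'   selecting on training loss is blind to the test set.
#' @param spec optional [synth_spec()] overriding the defaults.
#' @param output_dir optional directory for the JSON report, per-epoch CSV
#'   history, checkpoints and manifest.
#' @return Tibble with one row per trained model: `model`, `n_classes`,
#'   `n_parameters`, `test_accuracy`; trained models and reports attached
#'   as attributes `models` and `reports`.
#' @export
run_synth_experiment <- function(n_classes = 2L,
                                 model = c("gcnn", "baseline", "both"),
                                 seed = 1L, epochs = 200L,
                                 learning_rate = 0.005, batch_size = 32L,
                                 kappa = 5, n_restarts = 3L, spec = NULL,
                                 output_dir = NULL) {
  model <- match.arg(model)
  which_models <- if (model == "both") c("gcnn", "baseline") else model
  if (is.null(spec))
    spec <- synth_spec(n_classes = n_classes, seed = seed)
  n_classes <- spec$n_classes
  ds <- generate_dataset(spec)
  models <- list(); reports <- list(); rows <- list()
  for (m in which_models) {
    net <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      off <- (r - 1L) * 1000L
      cand <- if (m == "gcnn") {
        build_classifier(classifier_config(n_classes = n_classes,
                                           kappa = kappa,
                                           seed = seed + 20L + off))
      } else {
        build_mlp_baseline(mlp_config(
          layer_widths = c(spec$n_directions, 50L, 30L, n_classes),
          kappa = kappa, seed = seed + 20L + off))
      }
      tcfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                           batch_size = batch_size, seed = seed + 10L + off)
      cand <- train_model(cand, ds, tcfg)
      if (is.null(net) ||
          utils::tail(cand$history$loss, 1) < utils::tail(net$history$loss, 1))
        net <- cand
    }
    tcfg <- net$train_config
    rep <- evaluate_model(net, ds)
    models[[m]] <- net
    reports[[m]] <- rep
    rows[[m]] <- tibble::tibble(model = m, n_classes = n_classes,
                                n_parameters = count_parameters(net),
                                test_accuracy = rep$overall_accuracy)
    if (!is.null(output_dir)) {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(net$history,
                       file.path(output_dir, paste0("history_", m, ".csv")),
                       row.names = FALSE)
      write_checkpoint(net, file.path(output_dir,
                                      paste0("checkpoint_", m, ".json")))
      jsonlite::write_json(
        list(model = m, n_classes = n_classes,
             n_parameters = count_parameters(net),
             overall_accuracy = rep$overall_accuracy,
             per_class = rep$per_class,
             confusion_matrix = rep$confusion_matrix),
        file.path(output_dir, paste0("report_", m, ".json")),
        auto_unbox = TRUE, digits = NA, force = TRUE)
    }
  }
  res <- dplyr_bind(rows)
  if (!is.null(output_dir))
    .write_manifest(output_dir, list(
      task = "synth", spec = unclass(spec), train = unclass(tcfg),
      kappa = kappa, n_restarts = n_restarts, models = which_models,
      seed = seed))
  attr(res, "models") <- models
  attr(res, "reports") <- reports
  res
}

#' Run a voxel-classification experiment on a DWI scan
#'
#' Loads the 4D scan and gradient tables, extracts one shell, optionally
#' normalises by the voxel-wise mean b0, trains the spherical classifier on
#' the labelled voxels (optionally a per-class subsample), predicts every
#' labelled voxel, and evaluates against the provided truth.
#'
#' @param image_path,bval_path,bvec_path,labels_path input files (4D NIfTI,
#'   FSL tables, 3D integer label NIfTI; label 0 = background).
#' @param b_target shell b-value to use.
#' @param normalize divide by the voxel-wise mean b0.
#' @param subsample optional per-class training voxel counts
#'   (see [subsample_training_voxels()]).
#' @param kappa,learning_rate,epochs,batch_size,focal_gamma,focal_alpha
#'   model/training settings (defaults follow the tissue-task settings:
#'   kappa 10, lr 0.001, focal gamma 2).
#' @param seed master seed.
#' @param output_dir optional output directory for the predicted label
#'   volume, report and manifest.
#' @return List with `report` ([eval_report()]), `model`, `prediction` (3D
#'   array, same grid as the labels, 0 = background), and `paths`.
#' @export
run_dwi_experiment <- function(image_path, bval_path, bvec_path, labels_path,
                               b_target, normalize = TRUE, subsample = NULL,
                               kappa = 10, learning_rate = 0.001,
                               epochs = 20L, batch_size = 32L,
                               focal_gamma = 2, focal_alpha = NULL,
                               seed = 1L, output_dir = NULL) {
  missing_files <- Filter(Negate(file.exists),
                          c(image_path, bval_path, bvec_path, labels_path))
  if (length(missing_files))
    stop("missing input files: ", paste(missing_files, collapse = ", "))
  dwi <- load_dwi(image_path, bval_path, bvec_path)
  labimg <- RNifti::readNifti(labels_path)
  labels <- round(as.array(labimg))
  sh <- extract_shell(dwi$data, dwi$gradients, b_target)
  shell <- sh$shell
  if (normalize) shell <- normalize_by_b0(sh$shell, sh$b0)$normalized
  lvs <- labeled_voxel_set(shell, sh$directions, labels)
  keep <- vapply(lvs$signals, function(s) all(is.finite(s$values)),
                 logical(1))
  lvs$signals <- lvs$signals[keep]
  lvs$labels <- lvs$labels[keep]
  lvs$voxel_idx <- lvs$voxel_idx[keep]
  n_classes <- length(lvs$classes)
  net <- build_classifier(classifier_config(n_classes = n_classes,
                                            kappa = kappa,
                                            seed = seed + 20L))
  train_sel <- seq_along(lvs$labels)
  if (!is.null(subsample)) {
    sub <- subsample_training_voxels(lvs$labels, subsample, seed = seed)
    train_sel <- sort(unlist(sub, use.names = FALSE))
  }
  X <- prepare_classifier_inputs(net, lvs$signals)
  tcfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                       focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                       batch_size = batch_size, seed = seed + 10L)
  net <- train_model(net, list(x = X[.rows_for(train_sel), , drop = FALSE],
                               y = lvs$labels[train_sel]), tcfg)
  p <- .cls_forward(net$params, X, net$perm, .cls_dims(net))$p
  pred0 <- max.col(p, ties.method = "first") - 1L
  report <- eval_report(lvs$labels, pred0, n_classes = n_classes)
  prediction <- array(0, dim = dim(labels))
  prediction[lvs$voxel_idx] <- lvs$classes[pred0 + 1L]
  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    pred_path <- file.path(output_dir, "prediction_labels.nii")
    RNifti::writeNifti(RNifti::asNifti(prediction, reference = labimg),
                       pred_path)
    jsonlite::write_json(
      list(b_target = b_target, n_classes = n_classes,
           overall_accuracy = report$overall_accuracy,
           per_class = report$per_class,
           confusion_matrix = report$confusion_matrix),
      file.path(output_dir, "report_dwi.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(net$history, file.path(output_dir, "history_dwi.csv"),
                     row.names = FALSE)
    write_checkpoint(net, file.path(output_dir, "checkpoint_dwi.json"))
    .write_manifest(output_dir, list(
      task = "dwi", b_target = b_target, normalize = normalize,
      subsample = subsample, kappa = kappa, train = unclass(tcfg),
      seed = seed,
      inputs = list(image = image_path, bval = bval_path,
                    bvec = bvec_path, labels = labels_path)))
    paths <- list(prediction = pred_path)
  }
  list(report = report, model = net, prediction = prediction, paths = paths)
}
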