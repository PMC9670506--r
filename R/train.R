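#' Training and evaluation
#'
#' Focal-loss minibatch training with analytic gradients (verified against
#' finite differences in the test suite), Adam updates, optional early
#' stopping on a monitored class's validation accuracy, and confusion-matrix
#' metrics (overall accuracy, per-class recall, per-class Dice).
#'
#' @name training-eval
NULL

.cls_dims <- function(model) {
  cfg <- model$config
  list(K = nrow(model$grid$offsets), Cin = cfg$n_input_channels,
       CL = cfg$n_lift_channels, CG = cfg$n_conv_channels,
       nr = cfg$n_rays, ncls = cfg$n_classes)
}

# rows of the stacked (sample, vertex) matrix belonging to samples `idx`
.rows_for <- function(idx, n_vert = 12L) {
  rep((idx - 1L) * n_vert, each = n_vert) + seq_len(n_vert)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Resample a dataset onto a classifier's chart sample points
#'
#' Computes, per sample, the Watson weight matrix from its directions to the
#' model's 12 x K chart sample points and applies it to the values. The
#' result is the stacked input matrix consumed by the network: row
#' `(n-1)*12 + v` holds sample `n`, vertex `v`; column `(c-1)*K + j` holds
#' channel `c`, grid offset `j`.
#'
#' @param model a [build_classifier()] model.
#' @param newdata a [spherical_signal()], list of them, or dataset tibble
#'   with `directions`/`values` list columns.
#' @return Numeric matrix `(n_samples*12, n_channels*K)`.
#' @export
prepare_classifier_inputs <- function(model, newdata) {
  signals <- .as_signal_list(newdata)
  K <- nrow(model$grid$offsets)
  Nc <- model$config$n_input_channels
  kappa <- model$config$kappa
  out <- vector("list", length(signals))
  for (n in seq_along(signals)) {
    s <- signals[[n]]
    if (ncol(s$values) != Nc)
      stop("signal has ", ncol(s$values), " channel(s); model expects ", Nc)
    W <- watson_weight_matrix(s$directions, model$query, kappa)
    q <- W %*% s$values                       # (12K) x Nc, offset fastest
    qa <- array(q, dim = c(K, 12, Nc))
    out[[n]] <- matrix(aperm(qa, c(2, 1, 3)), 12, K * Nc)
  }
  do.call(rbind, out)
}

#' Interpolate a dataset onto its fixed base directions (baseline input)
#'
#' The dense baseline consumes raw per-direction values: each sample's
#' (rotated) signal is Watson-interpolated back onto the dataset's shared
#' base directions, yielding one feature vector per sample.
#'
#' @param model a [build_mlp_baseline()] model (supplies `kappa`).
#' @param newdata dataset tibble carrying a `base_directions` attribute, or
#'   a list of signals plus explicit `queries`.
#' @param queries optional M x 3 query directions (defaults to the
#'   dataset's base directions).
#' @return Numeric matrix `(n_samples, M)`.
#' @export
prepare_mlp_inputs <- function(model, newdata, queries = NULL) {
  if (is.null(queries)) queries <- attr(newdata, "base_directions")
  if (is.null(queries))
    stop("no query directions: pass `queries` or a dataset with a base_directions attribute")
  kappa <- model$config$kappa
  signals <- .as_signal_list(newdata)
  t(vapply(signals, function(s) {
    W <- watson_weight_matrix(s$directions, queries, kappa)
    as.numeric(W %*% s$values[, 1])
  }, numeric(nrow(queries))))
}

.as_signal_list <- function(newdata) {
  if (inherits(newdata, "bgcnn_signal")) return(list(newdata))
  if (is.data.frame(newdata)) {
    return(lapply(seq_len(nrow(newdata)), function(i)
      spherical_signal(newdata$directions[[i]], newdata$values[[i]])))
  }
  if (is.list(newdata)) return(newdata)
  stop("cannot interpret input of class ", paste(class(newdata), collapse = "/"))
}

# --- classifier forward/backward (batched, stacked-row layout) -------------

.make_wl_mat <- function(lift_w) {
  d <- dim(lift_w)                            # (Cin, CL, K)
  matrix(aperm(lift_w, c(3, 1, 2)), d[3] * d[1], d[2])
}

.make_wg_big <- function(conv_w, nr) {
  d <- dim(conv_w)                            # (CL, CG, nr)
  W <- matrix(0, nr * d[1], nr * d[2])
  for (r in seq_len(nr) - 1L) {
    for (s in seq_len(nr) - 1L) {
      W[r * d[1] + seq_len(d[1]), s * d[2] + seq_len(d[2])] <-
        conv_w[, , ((r - s) %% nr) + 1L]
    }
  }
  W
}

.cls_forward <- function(params, X, perm, dims) {
  K <- dims$K; Cin <- dims$Cin; CL <- dims$CL; CG <- dims$CG; nr <- dims$nr
  N12 <- nrow(X)
  N <- N12 %/% 12L
  WL <- .make_wl_mat(params$lift_w)
  colperm <- lapply(seq_len(nr), function(k)
    as.vector(outer(perm[k, ], (seq_len(Cin) - 1L) * K, "+")))
  F0 <- matrix(0, N12, nr * CL)
  for (k in seq_len(nr))
    F0[, (k - 1L) * CL + seq_len(CL)] <- X[, colperm[[k]], drop = FALSE] %*% WL
  F0 <- F0 + matrix(rep(params$lift_b, nr), N12, nr * CL, byrow = TRUE)
  A <- relu(F0)
  WG <- .make_wg_big(params$conv_w, nr)
  F1 <- A %*% WG +
    matrix(rep(params$conv_b, nr), N12, nr * CG, byrow = TRUE)
  B <- relu(F1)
  M <- B[, seq_len(CG), drop = FALSE]
  amax <- matrix(1L, N12, CG)
  for (s in 2:nr) {
    blk <- B[, (s - 1L) * CG + seq_len(CG), drop = FALSE]
    upd <- blk > M
    M[upd] <- blk[upd]
    amax[upd] <- s
  }
  flat <- t(matrix(aperm(array(M, c(12, N, CG)), c(3, 1, 2)), CG * 12L, N))
  logits <- flat %*% params$fc_w +
    matrix(params$fc_b, N, dims$ncls, byrow = TRUE)
  p <- .softmax(logits)
  list(p = p, logits = logits, flat = flat, amax = amax,
       mask1 = F1 > 0, mask0 = F0 > 0, A = A, X = X,
       colperm = colperm, WG = WG)
}

.cls_backward <- function(params, cache, dlogits, dims) {
  K <- dims$K; Cin <- dims$Cin; CL <- dims$CL; CG <- dims$CG; nr <- dims$nr
  N <- nrow(dlogits)
  N12 <- N * 12L
  g <- list()
  g$fc_w <- crossprod(cache$flat, dlogits)
  g$fc_b <- colSums(dlogits)
  dflat <- dlogits %*% t(params$fc_w)         # N x (12*CG), channel fastest
  dM <- matrix(aperm(array(t(dflat), c(CG, 12L, N)), c(2, 3, 1)), N12, CG)
  dB <- matrix(0, N12, nr * CG)
  for (s in seq_len(nr)) {
    sel <- cache$amax == s
    blk <- matrix(0, N12, CG)
    blk[sel] <- dM[sel]
    dB[, (s - 1L) * CG + seq_len(CG)] <- blk
  }
  dF1 <- dB * cache$mask1
  dA <- dF1 %*% t(cache$WG)
  dWG <- crossprod(cache$A, dF1)
  g$conv_w <- array(0, dim = dim(params$conv_w))
  for (r in seq_len(nr) - 1L) {
    for (s in seq_len(nr) - 1L) {
      m <- ((r - s) %% nr) + 1L
      g$conv_w[, , m] <- g$conv_w[, , m] +
        dWG[r * CL + seq_len(CL), s * CG + seq_len(CG), drop = FALSE]
    }
  }
  g$conv_b <- colSums(matrix(aperm(array(dF1, c(N12, CG, nr)), c(1, 3, 2)),
                             N12 * nr, CG))
  dF0 <- dA * cache$mask0
  dWL <- matrix(0, K * Cin, CL)
  lb <- numeric(CL)
  for (k in seq_len(nr)) {
    blk <- dF0[, (k - 1L) * CL + seq_len(CL), drop = FALSE]
    dWL <- dWL + crossprod(cache$X[, cache$colperm[[k]], drop = FALSE], blk)
    lb <- lb + colSums(blk)
  }
  g$lift_w <- aperm(array(dWL, c(K, Cin, CL)), c(2, 3, 1))
  g$lift_b <- lb
  g
}

# --- MLP forward/backward --------------------------------------------------

.layer_norm_fwd <- function(z, g, s, eps = 1e-5) {
  mu <- rowMeans(z)
  va <- rowMeans((z - mu)^2)
  sd <- sqrt(va + eps)
  zhat <- (z - mu) / sd
  list(y = sweep(sweep(zhat, 2, g, "*"), 2, s, "+"), zhat = zhat, sd = sd)
}

.layer_norm_bwd <- function(dy, ln, g) {
  dzhat <- sweep(dy, 2, g, "*")
  dg <- colSums(dy * ln$zhat)
  ds <- colSums(dy)
  dz <- (dzhat - rowMeans(dzhat) - ln$zhat * rowMeans(dzhat * ln$zhat)) / ln$sd
  list(dz = dz, dg = dg, ds = ds)
}

.mlp_forward <- function(params, X, config) {
  w <- config$layer_widths
  L <- length(w) - 1L
  h <- X
  caches <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    z <- h %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(h), w[l + 1], byrow = TRUE)
    cache <- list(h_in = h, z = z)
    if (config$hidden_norm) {
      ln <- .layer_norm_fwd(z, params[[paste0("g", l)]], params[[paste0("s", l)]])
      cache$ln <- ln
      y <- ln$y
    } else y <- z
    cache$y <- y
    h <- relu(y)
    caches[[l]] <- cache
  }
  logits <- h %*% params[[paste0("W", L)]] +
    matrix(params[[paste0("b", L)]], nrow(h), w[L + 1], byrow = TRUE)
  list(p = .softmax(logits), logits = logits, h_last = h, caches = caches)
}

.mlp_backward <- function(params, fwd, X, dlogits, config) {
  w <- config$layer_widths
  L <- length(w) - 1L
  g <- list()
  g[[paste0("W", L)]] <- crossprod(fwd$h_last, dlogits)
  g[[paste0("b", L)]] <- colSums(dlogits)
  dh <- dlogits %*% t(params[[paste0("W", L)]])
  for (l in rev(seq_len(L - 1L))) {
    cache <- fwd$caches[[l]]
    dy <- dh * (cache$y > 0)
    if (config$hidden_norm) {
      bw <- .layer_norm_bwd(dy, cache$ln, params[[paste0("g", l)]])
      g[[paste0("g", l)]] <- bw$dg
      g[[paste0("s", l)]] <- bw$ds
      dz <- bw$dz
    } else dz <- dy
    g[[paste0("W", l)]] <- crossprod(cache$h_in, dz)
    g[[paste0("b", l)]] <- colSums(dz)
    dh <- dz %*% t(params[[paste0("W", l)]])
  }
  g
}

# --- focal loss ------------------------------------------------------------

#' Focal loss
#'
#' `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)` for the true class's
#' predicted probability `p_t`, down-weighting well-classified samples;
#' `gamma = 0` with unit weights recovers cross-entropy. Probabilities are
#' clamped below at `eps` rather than erroring. Batch reduction is the mean.
#'
#' @param probabilities class-probability vector, or a matrix with one row
#'   per sample.
#' @param label 0-based true class index (vector for a batch).
#' @param gamma focusing exponent, >= 0.
#' @param alpha per-class weight vector (recycled scalar allowed).
#' @param eps clamp for `p_t`.
#' @return Mean focal loss (scalar).
#' @export
focal_loss <- function(probabilities, label, gamma = 2, alpha = 1,
                       eps = 1e-8) {
  p <- if (is.null(dim(probabilities))) matrix(probabilities, nrow = 1)
       else probabilities
  if (gamma < 0) stop("gamma must be >= 0")
  y <- as.integer(label)
  alpha <- rep_len(alpha, ncol(p))
  t <- pmax(p[cbind(seq_len(nrow(p)), y + 1L)], eps)
  mean(-alpha[y + 1L] * (1 - t)^gamma * log(t))
}

# gradient of the mean focal loss w.r.t. the logits
.focal_dlogits <- function(p, y, gamma, alpha, eps = 1e-8) {
  N <- nrow(p)
  alpha <- rep_len(alpha, ncol(p))
  t_raw <- p[cbind(seq_len(N), y + 1L)]
  t <- pmax(t_raw, eps)
  a <- alpha[y + 1L]
  term1 <- if (gamma > 0) a * gamma * (1 - t)^(gamma - 1) * log(t) else 0
  dLdt <- term1 - a * (1 - t)^gamma / t
  D <- -p * (dLdt * t_raw)                    # -dLdt * t * p_j
  D[cbind(seq_len(N), y + 1L)] <- D[cbind(seq_len(N), y + 1L)] + dLdt * t_raw
  D / N
}

# --- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- training --------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam step size (0.005 for the synthetic task, 0.001
#'   for the tissue tasks).
#' @param epochs training epochs.
#' @param focal_gamma focal-loss focusing exponent (0 = cross-entropy).
#' @param focal_alpha per-class focal weights; `NULL` = unit weights.
#' @param batch_size minibatch size.
#' @param seed seed for shuffling (weight init is seeded in the model).
#' @param early_stop optional `list(class = <0-based index>, patience = 5)`:
#'   stop when that class's validation accuracy has not improved for
#'   `patience` epochs.
#' @return A `bgcnn_train_config` list.
#' @export
train_config <- function(learning_rate = 0.005, epochs = 200L,
                         focal_gamma = 0, focal_alpha = NULL,
                         batch_size = 32L, seed = 1L, early_stop = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, focal_gamma >= 0, batch_size >= 1)
  if (!is.null(focal_alpha) &&
      (any(focal_alpha <= 0) || any(focal_alpha > 1)))
    stop("focal_alpha entries must lie in (0, 1]")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop = early_stop),
            class = "bgcnn_train_config")
}

#' Train a model with focal loss and Adam
#'
#' Accepts the spherical classifier or the dense baseline together with
#' either a dataset tibble (rows with `split == "train"` are used;
#' `split == "validation"` rows, if any, drive the optional early stopping)
#' or a prepared `list(x = <input matrix>, y = <0-based labels>)`.
#'
#' @param model a [build_classifier()] or [build_mlp_baseline()] model.
#' @param data dataset tibble from [generate_dataset()] or a prepared list.
#' @param config a [train_config()].
#' @return The trained model, with a `history` tibble (epoch, mean loss,
#'   validation metrics when available) and the config attached.
#' @export
train_model <- function(model, data, config = train_config()) {
  is_cls <- inherits(model, "bgcnn_classifier")
  prep <- .prepare_training_data(model, data)
  X <- prep$x; y <- prep$y
  if (length(y) == 0) stop("empty training set")
  ncls <- if (is_cls) model$config$n_classes
          else utils::tail(model$config$layer_widths, 1)
  alpha <- if (is.null(config$focal_alpha)) rep(1, ncls) else config$focal_alpha
  params <- model$params
  state <- .adam_init(params)
  dims <- if (is_cls) .cls_dims(model) else NULL
  n <- length(y)
  history <- vector("list", config$epochs)
  best_acc <- -Inf; stale <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        yb <- y[idx]
        if (is_cls) {
          Xb <- X[.rows_for(idx), , drop = FALSE]
          fwd <- .cls_forward(params, Xb, model$perm, dims)
        } else {
          Xb <- X[idx, , drop = FALSE]
          fwd <- .mlp_forward(params, Xb, model$config)
        }
        loss <- focal_loss(fwd$p, yb, config$focal_gamma, alpha)
        dlogits <- .focal_dlogits(fwd$p, yb, config$focal_gamma, alpha)
        grads <- if (is_cls) .cls_backward(params, fwd, dlogits, dims)
                 else .mlp_backward(params, fwd, Xb, dlogits, model$config)
        upd <- .adam_step(params, grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
        losses <- c(losses, loss)
      }
      rec <- list(epoch = epoch, loss = mean(losses))
      if (!is.null(prep$xval)) {
        model$params <- params
        pv <- if (is_cls) .cls_forward(params, prep$xval, model$perm, dims)$p
              else .mlp_forward(params, prep$xval, model$config)$p
        predv <- max.col(pv, ties.method = "first") - 1L
        rec$val_accuracy <- mean(predv == prep$yval)
        if (!is.null(config$early_stop)) {
          cls <- config$early_stop$class
          sel <- prep$yval == cls
          rec$val_monitor_accuracy <- if (any(sel)) mean(predv[sel] == cls) else NA_real_
          acc <- rec$val_monitor_accuracy
          if (!is.na(acc) && acc > best_acc + 1e-12) {
            best_acc <- acc; stale <- 0L
          } else stale <- stale + 1L
        }
      }
      history[[epoch]] <- tibble::as_tibble(rec)
      if (!is.null(config$early_stop) &&
          stale >= (config$early_stop$patience %||% 5L)) break
    }
  })
  model$params <- params
  model$history <- structure(dplyr_bind(history), class = c("bgcnn_history",
                                                            "tbl_df", "tbl",
                                                            "data.frame"))
  model$train_config <- config
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dplyr_bind <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  do.call(rbind, lst)
}

.prepare_training_data <- function(model, data) {
  is_cls <- inherits(model, "bgcnn_classifier")
  if (is.list(data) && !is.data.frame(data) && !is.null(data$x)) {
    return(list(x = data$x, y = as.integer(data$y),
                xval = data$xval, yval = if (is.null(data$yval)) NULL
                                        else as.integer(data$yval)))
  }
  stopifnot(is.data.frame(data))
  split <- if ("split" %in% names(data)) data$split else rep("train", nrow(data))
  tr <- data[split == "train", ]
  va <- data[split == "validation", ]
  prep1 <- function(d) {
    if (nrow(d) == 0) return(NULL)
    if (is_cls) prepare_classifier_inputs(model, d)
    else prepare_mlp_inputs(model, d,
                            queries = attr(data, "base_directions"))
  }
  list(x = prep1(tr), y = as.integer(tr$label),
       xval = prep1(va),
       yval = if (nrow(va)) as.integer(va$label) else NULL)
}

# --- evaluation ------------------------------------------------------------

#' Confusion-matrix metrics from labels
#'
#' @param truth,pred integer 0-based class labels.
#' @param n_classes number of classes (defaults to the range of `truth`).
#' @return Object of class `bgcnn_eval`: confusion matrix (rows = truth),
#'   overall accuracy, and a per-class tibble with recall (= per-class
#'   accuracy, `TP / (TP + FN)`; `NA` and flagged when the class is absent
#'   from the truth) and Dice (`2TP / (2TP + FP + FN)`).
#' @export
eval_report <- function(truth, pred, n_classes = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  if (is.null(n_classes)) n_classes <- max(truth, pred) + 1L
  lv <- seq_len(n_classes) - 1L
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- unclass(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  recall <- ifelse(rowSums(cm) > 0, tp / (tp + fn), NA_real_)
  dice <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  structure(list(
    confusion_matrix = cm,
    overall_accuracy = sum(tp) / sum(cm),
    per_class = tibble::tibble(class = lv, n_true = rowSums(cm),
                               recall = as.numeric(recall),
                               dice = as.numeric(dice),
                               undefined = rowSums(cm) == 0)
  ), class = "bgcnn_eval")
}

#' Evaluate a model on a dataset
#'
#' Predicts the rows with `split == "test"` (all rows if there is no split
#' column) and summarises the confusion matrix.
#'
#' @param model trained model.
#' @param dataset dataset tibble.
#' @return A [eval_report()] object.
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(is.data.frame(dataset))
  d <- if ("split" %in% names(dataset)) dataset[dataset$split == "test", ]
       else dataset
  attr(d, "base_directions") <- attr(dataset, "base_directions")
  pred <- stats::predict(model, d, type = "class")
  ncls <- if (inherits(model, "bgcnn_classifier")) model$config$n_classes
          else utils::tail(model$config$layer_widths, 1)
  eval_report(d$label, pred, n_classes = ncls)
}

#' @export
print.bgcnn_eval <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  print(x$per_class)
  invisible(x)
}
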