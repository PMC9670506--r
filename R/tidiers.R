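#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x a [eval_report()] object.
#' @param ... unused.
#' @return The per-class tibble (class, support, recall, Dice).
#' @export
tidy.bgcnn_eval <- function(x, ...) x$per_class

#' @rdname tidy.bgcnn_eval
#' @export
glance.bgcnn_eval <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 n = sum(x$confusion_matrix),
                 n_classes = nrow(x$confusion_matrix))
}

#' Tidy a fitted classifier
#'
#' One row per trainable tensor with its dimensions and size.
#'
#' @param x a `bgcnn_classifier` or `bgcnn_mlp`.
#' @param ... unused.
#' @return Tibble with `term`, `dims`, `n_parameters`.
#' @export
tidy.bgcnn_classifier <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    dims = vapply(x$params, function(p)
      paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x"),
      character(1)),
    n_parameters = vapply(x$params, length, integer(1)))
}

#' @rdname tidy.bgcnn_classifier
#' @export
tidy.bgcnn_mlp <- tidy.bgcnn_classifier

#' @rdname tidy.bgcnn_classifier
#' @export
glance.bgcnn_classifier <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x),
    n_classes = x$config$n_classes,
    trained = !is.null(x$history),
    final_loss = if (is.null(x$history)) NA_real_
                 else utils::tail(x$history$loss, 1))
}

#' @rdname tidy.bgcnn_classifier
#' @export
glance.bgcnn_mlp <- function(x, ...) {
  tibble::tibble(
    n_parameters = count_parameters(x),
    n_classes = utils::tail(x$config$layer_widths, 1),
    trained = !is.null(x$history),
    final_loss = if (is.null(x$history)) NA_real_
                 else utils::tail(x$history$loss, 1))
}

#' Plot a training history
#'
#' Loss per epoch (and validation accuracy when recorded).
#'
#' @param object a `bgcnn_history` tibble (the `history` element of a
#'   trained model).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.bgcnn_history <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss")
  if ("val_accuracy" %in% names(df)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$val_accuracy), linetype = "dashed",
      colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Plot per-class metrics of an evaluation report
#'
#' @param object a [eval_report()] object.
#' @param ... unused.
#' @return A ggplot object with recall and Dice per class.
#' @export
autoplot.bgcnn_eval <- function(object, ...) {
  df <- object$per_class
  long <- tibble::tibble(
    class = rep(df$class, 2),
    metric = rep(c("recall", "dice"), each = nrow(df)),
    value = c(df$recall, df$dice))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "class", y = NULL, fill = NULL)
}
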