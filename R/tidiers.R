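# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for the
# package's result objects.

#' Tidy a triplet LSTM fit into its per-epoch history
#'
#' @param x A `triplet_lstm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `ce`, `margin_loss`,
#'   `total`, `val_accuracy`.
#' @export
tidy.triplet_lstm_fit <- function(x, ...) x$history

#' One-row summary of a triplet LSTM fit
#'
#' @param x A `triplet_lstm_fit`.
#' @param ... Unused.
#' @export
glance.triplet_lstm_fit <- function(x, ...) {
  tibble(setup = x$train_cfg$setup, lambda = x$train_cfg$lambda,
         margin = x$train_cfg$margin, epochs = nrow(x$history),
         best_epoch = x$best_epoch, best_val_accuracy = x$best_val_accuracy,
         n_params = length(x$model$params))
}

#' Tidy per-class metrics
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble (precision, recall, f1, support).
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row macro metrics
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
glance.metrics_report <- function(x, ...) x$metrics

#' Tidy multirun results
#'
#' @param x A `triplet_lstm_multirun`.
#' @param ... Unused.
#' @return Per-run metric tibble.
#' @export
tidy.triplet_lstm_multirun <- function(x, ...) x$per_run

#' Mean and standard deviation over runs
#'
#' @param x A `triplet_lstm_multirun`.
#' @param ... Unused.
#' @export
glance.triplet_lstm_multirun <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"))
}

#' Plot training curves
#'
#' Loss components and validation accuracy per epoch; the best epoch is
#' marked.
#'
#' @param object A `triplet_lstm_fit`.
#' @param ... Unused.
#' @export
autoplot.triplet_lstm_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("ce", "margin_loss", "total", "val_accuracy"),
                        names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot a normalized confusion matrix
#'
#' @param object A `metrics_report`.
#' @param normalize `"recall"` (rows sum to 1) or `"precision"` (columns sum
#'   to 1).
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object,
                                    normalize = c("recall", "precision"),
                                    ...) {
  normalize <- match.arg(normalize)
  m <- object$confusion[[normalize]]
  df <- as_tibble(as.data.frame.table(m, responseName = "value"))
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(fill = normalize) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
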