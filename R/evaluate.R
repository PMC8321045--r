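# Classification metrics, confusion matrices, and embedding-discriminability
# diagnostics.
#
# Conventions (documented, deterministic): argmax ties break toward the
# lower class index; macro averages are unweighted means over all declared
# classes, with precision/recall of classes that received no predictions /
# have no samples set to 0; Cohen's kappa is (OA - p_e) / (1 - p_e) with
# chance agreement p_e from the confusion marginals.

#' Raw and normalized confusion matrices
#'
#' @param truth,pred Integer vectors of 0-based true and predicted labels.
#' @param n_classes Number of classes (matrix dimension).
#' @param class_names Optional dimnames.
#' @return An object of class `confusion_pair`: `raw` (counts, rows = truth,
#'   columns = prediction), `precision` (columns sum to 1 where non-empty)
#'   and `recall` (rows sum to 1 where non-empty).
#' @export
confusion_pair <- function(truth, pred, n_classes,
                           class_names = NULL) {
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  if (length(truth) == 0) abort("cannot build a confusion matrix from 0 samples")
  raw <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    raw[truth[i] + 1L, pred[i] + 1L] <- raw[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes) - 1L)
  dimnames(raw) <- list(truth = class_names, prediction = class_names)
  colsum <- colSums(raw)
  rowsum <- rowSums(raw)
  precision <- sweep(raw, 2, ifelse(colsum == 0, 1, colsum), `/`)
  recall <- sweep(raw, 1, ifelse(rowsum == 0, 1, rowsum), `/`)
  structure(list(raw = raw, precision = precision, recall = recall),
            class = "confusion_pair")
}

metrics_from_confusion <- function(cm) {
  raw <- cm$raw
  n <- sum(raw)
  diagv <- diag(raw)
  rowsum <- rowSums(raw)
  colsum <- colSums(raw)
  oa <- sum(diagv) / n
  pe <- sum(rowsum * colsum) / n^2
  kappa <- if (pe == 1) as.numeric(oa == 1) else (oa - pe) / (1 - pe)
  precision <- ifelse(colsum == 0, 0, diagv / colsum)
  recall <- ifelse(rowsum == 0, 0, diagv / rowsum)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  list(oa = oa, kappa = kappa, precision = precision, recall = recall,
       f1 = f1, n = n)
}

#' Evaluate a model on labeled parcels
#'
#' Predictions are the argmax of the class probabilities. Reports overall
#' accuracy, Cohen's kappa, macro-averaged f1/precision/recall (macro-f1 =
#' mean of per-class f1), per-class values, and the precision- and
#' recall-normalized confusion matrices.
#'
#' @param model A `triplet_lstm` or `triplet_lstm_fit`.
#' @param df A non-empty standardized parcel tibble with labels.
#' @return An object of class `metrics_report`.
#' @export
evaluate_model <- function(model, df) {
  if (nrow(df) == 0) abort("cannot evaluate on an empty sample list")
  model <- as_triplet_lstm(model)
  pred <- predict(model, df, type = "class")
  metrics_report(df$label, pred, model$config$n_classes, model$class_names)
}

#' Build a metrics report from labels and predictions
#'
#' @param truth,pred 0-based integer label vectors.
#' @param n_classes Declared class count (macro averages run over all of
#'   them, including empty classes).
#' @param class_names Optional class names.
#' @return An object of class `metrics_report` with elements `metrics`
#'   (one-row tibble: `overall_accuracy`, `kappa`, `mean_f1`,
#'   `mean_precision`, `mean_recall`, `n_samples`), `per_class`, and
#'   `confusion` (a [confusion_pair()]).
#' @export
metrics_report <- function(truth, pred, n_classes, class_names = NULL) {
  cm <- confusion_pair(truth, pred, n_classes, class_names)
  m <- metrics_from_confusion(cm)
  per_class <- tibble(
    class = seq_len(n_classes) - 1L,
    class_name = rownames(cm$raw),
    precision = as.numeric(m$precision),
    recall = as.numeric(m$recall),
    f1 = as.numeric(m$f1),
    support = as.integer(rowSums(cm$raw)))
  metrics <- tibble(
    overall_accuracy = m$oa, kappa = m$kappa,
    mean_f1 = mean(m$f1), mean_precision = mean(m$precision),
    mean_recall = mean(m$recall), n_samples = m$n)
  structure(list(metrics = metrics, per_class = per_class, confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<metrics_report> n=%d  OA=%.4f  kappa=%.4f  f1=%.4f  precision=%.4f  recall=%.4f\n",
    m$n_samples, m$overall_accuracy, m$kappa, m$mean_f1, m$mean_precision,
    m$mean_recall))
  invisible(x)
}

#' Embedding separation diagnostics
#'
#' Quantifies the discriminability the metric loss is meant to create:
#' the mean within-class pairwise Euclidean distance (pooled over all
#' same-class pairs; classes with fewer than 2 members contribute none and
#' are noted), the mean between-class centroid distance, and their ratio
#' (between / within — a Fisher-style separation score, `Inf` when all
#' within-class pairs coincide).
#'
#' @param embeddings Numeric matrix (rows = samples), or a tibble from
#'   [embed_parcels()] (uses its `embedding` and `label` columns).
#' @param labels 0-based integer labels; taken from the tibble if omitted.
#' @return A one-row tibble: `within`, `between`, `ratio`,
#'   `n_classes_used`.
#' @export
embedding_separation <- function(embeddings, labels = NULL) {
  if (is.data.frame(embeddings)) {
    if (is.null(labels)) labels <- embeddings$label
    embeddings <- do.call(rbind, embeddings$embedding)
  }
  if (is.null(labels)) abort("labels are required")
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("embedding separation needs >= 2 classes")

  wsum <- 0; wn <- 0; used <- 0L
  centroids <- matrix(NA_real_, length(classes), ncol(embeddings))
  for (i in seq_along(classes)) {
    rows <- embeddings[labels == classes[i], , drop = FALSE]
    centroids[i, ] <- colMeans(rows)
    if (nrow(rows) >= 2) {
      d <- stats::dist(rows)
      wsum <- wsum + sum(d)
      wn <- wn + length(d)
      used <- used + 1L
    } else {
      message(sprintf("class %s has < 2 members; no within-class pairs", classes[i]))
    }
  }
  if (wn == 0) abort("no class has >= 2 members; within-class distance undefined")
  within <- wsum / wn
  between <- mean(stats::dist(centroids))
  tibble(within = within, between = between,
         ratio = if (within == 0) Inf else between / within,
         n_classes_used = used)
}

#' Write a metrics report to JSON and CSV
#'
#' Companion to the evaluate workflow: metrics as a versioned JSON document,
#' confusion matrices as CSV files with class-name headers.
#'
#' @param report A `metrics_report`.
#' @param json_path Output JSON path, or `NULL` to skip.
#' @param confusion_prefix Path prefix for
#'   `<prefix>_{raw,precision,recall}.csv`, or `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, confusion_prefix = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(format = "tripletlstm-metrics", version = 1L,
           metrics = as.list(report$metrics),
           per_class = report$per_class),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(confusion_prefix)) {
    for (kind in c("raw", "precision", "recall")) {
      m <- report$confusion[[kind]]
      out <- cbind(truth = rownames(m), as_tibble(as.data.frame.matrix(m)))
      readr::write_csv(out, paste0(confusion_prefix, "_", kind, ".csv"),
                       progress = FALSE)
    }
  }
  invisible(report)
}
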