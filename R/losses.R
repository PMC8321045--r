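# Loss components: inverse-median-frequency class weights, weighted
# cross-entropy, the margin triplet hinge on embedding distances, and their
# weighted combination.

#' Inverse median frequency class weights
#'
#' For training frequencies `g(k) = count_k / total` and their median `g~`,
#' each class gets weight `w_k = g~ / g(k)`, so the identity
#' `w_k * g(k) = g~` holds exactly for every class, balanced data yields all
#' weights 1, and the rarest class always receives the largest weight.
#' Weights are computed on the training split only.
#'
#' @param labels Integer vector of 0-based training labels.
#' @param n_classes Number of classes; every class `0..n_classes-1` must
#'   appear at least once.
#' @return A tibble with columns `class`, `count`, `frequency`, `weight`.
#' @export
class_weights <- function(labels, n_classes) {
  n_classes <- as.integer(n_classes)
  if (any(labels < 0 | labels >= n_classes)) {
    abort(sprintf("labels must lie in [0, %d)", n_classes))
  }
  count <- tabulate(labels + 1L, nbins = n_classes)
  if (any(count == 0)) {
    abort(paste0("class(es) absent from the training labels: ",
                 paste(which(count == 0) - 1L, collapse = ", ")),
          class = "tripletlstm_weight_error")
  }
  g <- count / sum(count)
  tibble(class = seq_len(n_classes) - 1L, count = count, frequency = g,
         weight = median(g) / g)
}

as_weight_vector <- function(w, n_classes) {
  if (is.data.frame(w)) w <- w$weight
  if (length(w) != n_classes) {
    abort(sprintf("expected %d class weights, got %d", n_classes, length(w)))
  }
  if (any(!is.finite(w)) || any(w <= 0)) abort("class weights must be finite and > 0")
  w
}

one_hot_to_labels <- function(y, n_classes) {
  if (is.matrix(y)) {
    ok <- apply(y, 1, function(r) all(r %in% c(0, 1)) && sum(r) == 1)
    if (!all(ok)) abort("y rows must be one-hot vectors")
    max.col(y, ties.method = "first") - 1L
  } else {
    as.integer(y)
  }
}

#' Weighted cross-entropy loss
#'
#' `-w_c * log(p_c)` per sample, where `c` is the true class; the log
#' argument is clamped at 1e-12 so confident wrong predictions stay finite.
#'
#' @param probs Probability matrix (rows are samples, columns classes) or a
#'   single probability vector.
#' @param y Integer vector of 0-based labels, or a one-hot matrix (rows that
#'   are not one-hot raise an error).
#' @param weights Class-weight vector or a [class_weights()] tibble; defaults
#'   to unweighted (all 1).
#' @return Numeric vector of per-sample losses (all `>= 0`).
#' @export
weighted_cross_entropy <- function(probs, y, weights = NULL) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  n_classes <- ncol(probs)
  labels <- one_hot_to_labels(y, n_classes)
  if (length(labels) != nrow(probs)) {
    abort("number of labels must match number of probability rows")
  }
  if (any(labels < 0 | labels >= n_classes)) {
    abort(sprintf("labels must lie in [0, %d)", n_classes))
  }
  w <- if (is.null(weights)) rep(1, n_classes) else as_weight_vector(weights, n_classes)
  p_true <- probs[cbind(seq_along(labels), labels + 1L)]
  -w[labels + 1L] * log(pmax(p_true, 1e-12))
}

#' Margin triplet loss on embeddings
#'
#' Per triplet, `max(0, D(a,p) - D(a,n) + m)` with `D` the (non-squared)
#' Euclidean distance between embeddings; the batch value is the mean over
#' triplets. Invariant to a common rigid translation of all three embedding
#' sets.
#'
#' @param e_a,e_p,e_n Embedding matrices (rows are triplets) or single
#'   vectors, all of equal dimension.
#' @param margin Margin `m >= 0` (default 1).
#' @param reduce `"mean"` (default, the batch loss) or `"none"` for
#'   per-triplet values.
#' @return Non-negative scalar (or vector when `reduce = "none"`).
#' @export
triplet_loss <- function(e_a, e_p, e_n, margin = 1, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  if (!is.matrix(e_a)) e_a <- matrix(e_a, nrow = 1)
  if (!is.matrix(e_p)) e_p <- matrix(e_p, nrow = 1)
  if (!is.matrix(e_n)) e_n <- matrix(e_n, nrow = 1)
  if (!all(dim(e_a) == dim(e_p)) || !all(dim(e_a) == dim(e_n))) {
    abort("anchor, positive and negative embeddings must share dimensions")
  }
  if (margin < 0) abort("margin must be >= 0")
  d_ap <- sqrt(rowSums((e_a - e_p)^2))
  d_an <- sqrt(rowSums((e_a - e_n)^2))
  h <- pmax(0, d_ap - d_an + margin)
  if (reduce == "mean") mean(h) else h
}

#' Total triplet-network loss
#'
#' The sum of the three branch cross-entropies plus `lambda` times the
#' margin loss: `Lt = Lc(p) + Lc(a) + Lc(n) + lambda * Lm(p, a, n)`. Over a
#' batch each cross-entropy term is the batch mean of its role, and the
#' margin term the batch mean hinge, i.e. the per-triplet total averaged
#' over the batch.
#'
#' @param probs Named list with probability matrices `anchor`, `positive`,
#'   `negative`.
#' @param labels Named list with 0-based label vectors for the same roles.
#' @param embeddings Named list with embedding matrices for the same roles.
#' @param weights Class weights (vector or [class_weights()] tibble), or
#'   `NULL` for unweighted.
#' @param margin,lambda Margin `m >= 0` and combination weight
#'   `lambda >= 0` (defaults 1 and 1).
#' @return Scalar total loss with attributes `ce` (sum of the three
#'   cross-entropy means) and `margin_loss`.
#' @export
total_loss <- function(probs, labels, embeddings, weights = NULL,
                       margin = 1, lambda = 1) {
  if (lambda < 0) abort("lambda must be >= 0")
  roles <- c("anchor", "positive", "negative")
  if (!all(roles %in% names(probs)) || !all(roles %in% names(labels)) ||
      !all(roles %in% names(embeddings))) {
    abort("probs, labels and embeddings must be lists with anchor/positive/negative")
  }
  ce <- sum(vapply(roles, function(r) {
    mean(weighted_cross_entropy(probs[[r]], labels[[r]], weights))
  }, numeric(1)))
  lm <- triplet_loss(embeddings$anchor, embeddings$positive,
                     embeddings$negative, margin = margin)
  structure(ce + lambda * lm, ce = ce, margin_loss = lm)
}
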