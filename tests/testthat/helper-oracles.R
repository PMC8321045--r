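# Independent oracle implementations: deliberately naive scalar loops kept
# separate from the package's vectorized / compiled code paths.

oracle_cross_entropy <- function(prob_row, label0, w) {
  # -sum_k w_k y(k) log p_k with the same 1e-12 clamp
  s <- 0
  for (k in seq_along(prob_row)) {
    y_k <- as.numeric(k - 1 == label0)
    s <- s - w[k] * y_k * log(max(prob_row[k], 1e-12))
  }
  s
}

oracle_triplet_loss <- function(ea, ep, en, m) {
  d <- function(u, v) sqrt(sum((u - v)^2))
  max(0, d(ea, ep) - d(ea, en) + m)
}

oracle_metrics <- function(cm) {
  # textbook formulas from a raw confusion matrix (rows truth, cols pred)
  n <- sum(cm)
  K <- nrow(cm)
  oa <- sum(diag(cm)) / n
  pe <- 0
  for (k in seq_len(K)) pe <- pe + sum(cm[k, ]) * sum(cm[, k])
  pe <- pe / n^2
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    prec[k] <- if (sum(cm[, k]) == 0) 0 else tp / sum(cm[, k])
    rec[k] <- if (sum(cm[k, ]) == 0) 0 else tp / sum(cm[k, ])
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  list(oa = oa,
       kappa = if (pe == 1) as.numeric(oa == 1) else (oa - pe) / (1 - pe),
       mean_precision = mean(prec), mean_recall = mean(rec),
       mean_f1 = mean(f1))
}

oracle_even_indices <- function(t_raw, t_steps) {
  # brute-force even spacing at stride t_raw / t_steps (0-based floor rule)
  out <- integer(t_steps)
  for (j in seq_len(t_steps)) out[j] <- floor((j - 1) * t_raw / t_steps) + 1
  out
}
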