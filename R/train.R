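# Optimization loop: region-aware or naive triplet streams (or a plain
# single-branch cross-entropy stream), shared-weight forward/backward through
# the compiled encoder, Adam updates, per-epoch validation accuracy and
# strict-improvement early stopping.

#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with learning rate 0.001,
#' batch size 256, margin and lambda 1, inverse-median-frequency class
#' weighting, early stopping when validation accuracy stops improving.
#'
#' @param setup `"setup1"` (region-aware triplets), `"setup2"` (naive
#'   triplets) or `"none"` (single-branch weighted cross-entropy, the
#'   vanilla-LSTM objective).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Triplets (or samples, for `"none"`) per batch.
#' @param max_epochs Upper bound on epochs.
#' @param patience Epochs without strict validation-accuracy improvement
#'   before stopping (>= 1).
#' @param margin,lambda Triplet margin `m` and combination weight `lambda`.
#' @param weighting `"inverse_median_frequency"` or `"none"`.
#' @param triplets_per_epoch Triplet draws per epoch; default one per
#'   training sample (an "epoch" of anchors on average).
#' @param seed Integer seed covering initialization and all sampling.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   denominator offset.
#' @return A list of class `train_config`.
#' @export
train_config <- function(setup = c("setup1", "setup2", "none"),
                         learning_rate = 0.001, batch_size = 256L,
                         max_epochs = 20L, patience = 5L,
                         margin = 1, lambda = 1,
                         weighting = c("inverse_median_frequency", "none"),
                         triplets_per_epoch = NULL, seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  setup <- match.arg(setup)
  weighting <- match.arg(weighting)
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (patience < 1) abort("patience must be >= 1")
  if (margin < 0 || lambda < 0) abort("margin and lambda must be >= 0")
  structure(
    list(setup = setup, learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         margin = margin, lambda = lambda, weighting = weighting,
         triplets_per_epoch = triplets_per_epoch, seed = as.integer(seed),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         adam_eps = adam_eps),
    class = "train_config")
}

new_adam <- function(n, cfg) {
  list(m = numeric(n), v = numeric(n), t = 0L,
       lr = cfg$learning_rate, b1 = cfg$adam_beta1, b2 = cfg$adam_beta2,
       eps = cfg$adam_eps)
}

adam_update <- function(state, params, grad) {
  state$t <- state$t + 1L
  state$m <- state$b1 * state$m + (1 - state$b1) * grad
  state$v <- state$b2 * state$v + (1 - state$b2) * grad^2
  mhat <- state$m / (1 - state$b1^state$t)
  vhat <- state$v / (1 - state$b2^state$t)
  list(state = state,
       params = params - state$lr * mhat / (sqrt(vhat) + state$eps))
}

dropout_mask <- function(n, e, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(n * e) >= rate) / (1 - rate), n, e)
}

#' Train a triplet LSTM
#'
#' Per epoch: draw a triplet stream under the configured setup, run all
#' three members of each batch through the one shared encoder, combine the
#' three weighted cross-entropies with `lambda` times the margin loss,
#' backpropagate, and take an Adam step. Validation accuracy (plain
#' classification of the validation samples — no triplets at validation) is
#' evaluated after every epoch; the best checkpoint is kept and training
#' stops after `patience` epochs without strict improvement. Runs are fully
#' reproducible given `train_cfg$seed`.
#'
#' With `setup = "none"` the same loop trains a single branch under mean
#' weighted cross-entropy over shuffled training samples — the vanilla LSTM
#' this architecture degenerates to at `lambda = 0`.
#'
#' @param df A standardized parcel tibble with a `split` column
#'   ([split_by_region()]); training and validation splits must be
#'   non-empty.
#' @param encoder_cfg An [encoder_config()]; band/class counts default to
#'   the dataset's metadata.
#' @param train_cfg A [train_config()].
#' @param triplet_stream Advanced: a list (one element per epoch) of triplet
#'   tibbles indexing the training subset, overriding the per-epoch draws —
#'   used by equivalence harnesses.
#' @param sample_stream Advanced, for `setup = "none"`: a list (per epoch)
#'   of lists of training-row index vectors serving as batches.
#' @return An object of class `triplet_lstm_fit`: `model` (best
#'   checkpoint), `history` (per-epoch loss components and validation
#'   accuracy), `best_epoch`, `best_val_accuracy`, `class_weights`,
#'   `train_cfg`.
#' @export
train_triplet_lstm <- function(df, encoder_cfg = NULL,
                               train_cfg = train_config(),
                               triplet_stream = NULL, sample_stream = NULL) {
  if (!"split" %in% names(df)) abort("df needs a split column; see split_by_region()")
  meta <- parcel_meta(df)
  if (is.null(encoder_cfg)) {
    encoder_cfg <- encoder_config(n_bands = meta$n_bands,
                                  n_classes = meta$n_classes)
  }
  if (encoder_cfg$n_bands != meta$n_bands ||
      encoder_cfg$n_classes != meta$n_classes) {
    abort("encoder_config band/class counts do not match the dataset")
  }
  train_df <- df[df$split == "train", ]
  val_df <- df[df$split == "validation", ]
  if (nrow(train_df) == 0 || nrow(val_df) == 0) {
    abort("training and validation splits must both be non-empty")
  }
  cfg <- train_cfg
  ecfg <- encoder_cfg
  n_train <- nrow(train_df)
  count <- if (is.null(cfg$triplets_per_epoch)) n_train else cfg$triplets_per_epoch

  w <- if (cfg$weighting == "inverse_median_frequency") {
    cw <- class_weights(train_df$label, meta$n_classes)
    cw$weight
  } else {
    cw <- NULL
    rep(1, meta$n_classes)
  }

  arr <- series_array(train_df)
  val_arr <- series_array(val_df)
  E <- embedding_dim(ecfg)

  set.seed(cfg$seed)
  model <- init_triplet_lstm(ecfg, class_names = meta$class_names)
  opt <- new_adam(length(model$params), cfg)

  n_epochs <- if (!is.null(triplet_stream)) length(triplet_stream) else
    if (!is.null(sample_stream)) length(sample_stream) else cfg$max_epochs

  history <- vector("list", n_epochs)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(n_epochs)) {
    ce_acc <- 0; lm_acc <- 0; tot_acc <- 0; nb <- 0L
    if (cfg$setup == "none") {
      batches <- if (!is.null(sample_stream)) sample_stream[[epoch]] else {
        ord <- sample.int(n_train)
        split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      }
      for (b in batches) {
        mask <- dropout_mask(length(b), E, ecfg$dropout)
        st <- cpp_ce_step(arr[b, , , drop = FALSE], train_df$label[b],
                          model$params, w, ecfg$n_bands, ecfg$hidden_dim,
                          ecfg$num_layers, ecfg$bidirectional, ecfg$n_classes,
                          mask)
        if (!is.finite(st$loss)) {
          abort(sprintf("non-finite loss at epoch %d; try a lower learning rate",
                        epoch))
        }
        up <- adam_update(opt, model$params, st$grad)
        opt <- up$state; model$params <- up$params
        ce_acc <- ce_acc + st$loss; tot_acc <- tot_acc + st$loss
        nb <- nb + 1L
      }
      lm_acc <- NA_real_
    } else {
      triplets <- if (!is.null(triplet_stream)) triplet_stream[[epoch]] else
        sample_triplets(train_df, count, setup = cfg$setup)
      for (tb in triplet_batches(triplets, cfg$batch_size)) {
        nb_t <- nrow(tb)
        masks <- if (ecfg$dropout > 0) {
          list(anchor = dropout_mask(nb_t, E, ecfg$dropout),
               positive = dropout_mask(nb_t, E, ecfg$dropout),
               negative = dropout_mask(nb_t, E, ecfg$dropout))
        }
        st <- cpp_triplet_step(
          arr[tb$anchor, , , drop = FALSE], arr[tb$positive, , , drop = FALSE],
          arr[tb$negative, , , drop = FALSE],
          train_df$label[tb$anchor], train_df$label[tb$positive],
          train_df$label[tb$negative],
          model$params, w, cfg$lambda, cfg$margin,
          ecfg$n_bands, ecfg$hidden_dim, ecfg$num_layers, ecfg$bidirectional,
          ecfg$n_classes, masks)
        if (!is.finite(st$total)) {
          abort(sprintf("non-finite loss at epoch %d; try a lower learning rate",
                        epoch))
        }
        up <- adam_update(opt, model$params, st$grad)
        opt <- up$state; model$params <- up$params
        ce_acc <- ce_acc + st$ce_sum / 3  # per member evaluation
        lm_acc <- lm_acc + st$margin_loss
        tot_acc <- tot_acc + st$total
        nb <- nb + 1L
      }
    }

    val_emb <- encode_array(model, val_arr)
    val_pred <- max.col(classify(model, val_emb), ties.method = "first") - 1L
    acc <- mean(val_pred == val_df$label)

    history[[epoch]] <- tibble(
      epoch = epoch, ce = ce_acc / nb,
      margin_loss = if (is.na(lm_acc)) NA_real_ else lm_acc / nb,
      total = tot_acc / nb, val_accuracy = acc)

    if (acc > best$acc) {
      best <- list(acc = acc, params = model$params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }

  model$params <- best$params
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val_accuracy = best$acc,
         class_weights = cw, train_cfg = cfg),
    class = "triplet_lstm_fit")
}

#' @export
print.triplet_lstm_fit <- function(x, ...) {
  cat(sprintf(
    "<triplet_lstm_fit> setup=%s lambda=%g margin=%g | %d epoch(s), best validation accuracy %.4f at epoch %d\n",
    x$train_cfg$setup, x$train_cfg$lambda, x$train_cfg$margin,
    nrow(x$history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Train and evaluate across several seeded runs
#'
#' Repeats the train/evaluate cycle with distinct seeds (weight
#' initialization and triplet draws differ; the data split does not) and
#' reports per-metric mean and standard deviation, the convention used to
#' quote headline numbers as averages across runs.
#'
#' @param df A standardized, split parcel tibble.
#' @param encoder_cfg An [encoder_config()] or `NULL` for data defaults.
#' @param train_cfg A [train_config()]; its seed is replaced per run.
#' @param n_runs Number of runs (default 5).
#' @param seeds Integer vector of length `n_runs`; defaults to
#'   `train_cfg$seed + 0:(n_runs-1)`.
#' @param eval_split Which split to evaluate on (default `"test"`).
#' @return An object of class `triplet_lstm_multirun` with `per_run`
#'   (tibble of per-run metrics), `summary` (metric, mean, sd) and `fits`.
#' @export
multirun <- function(df, encoder_cfg = NULL, train_cfg = train_config(),
                     n_runs = 5L, seeds = NULL, eval_split = "test") {
  if (n_runs < 1) abort("n_runs must be >= 1")
  if (is.null(seeds)) seeds <- train_cfg$seed + seq_len(n_runs) - 1L
  if (length(seeds) != n_runs || anyDuplicated(seeds)) {
    abort("seeds must be n_runs distinct integers")
  }
  eval_df <- df[df$split == eval_split, ]
  runs <- purrr::map(seq_len(n_runs), function(r) {
    cfg <- train_cfg
    cfg$seed <- as.integer(seeds[r])
    fit <- train_triplet_lstm(df, encoder_cfg, cfg)
    rep <- evaluate_model(fit, eval_df)
    list(fit = fit, metrics = glance(rep))
  })
  per_run <- dplyr::bind_rows(purrr::map(runs, "metrics"), .id = "run") |>
    dplyr::mutate(run = as.integer(.data$run), seed = seeds[.data$run])
  summary <- per_run |>
    dplyr::select(-"run", -"seed") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     .groups = "drop")
  structure(list(per_run = per_run, summary = summary,
                 fits = purrr::map(runs, "fit")),
            class = "triplet_lstm_multirun")
}

#' @export
print.triplet_lstm_multirun <- function(x, ...) {
  cat(sprintf("<triplet_lstm_multirun> %d run(s)\n", nrow(x$per_run)))
  print(x$summary)
  invisible(x)
}
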