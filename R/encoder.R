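# R-side surface of the recurrent encoder: configuration, initialization,
# embedding, classification, and text checkpoints.
#
# The encoder f(.) maps a standardized T x B series to a fixed-length
# embedding: the concatenated last-step hidden states of the two directions
# of a (by default bidirectional, single-layer, 128-unit) LSTM, so the
# default embedding dimension is 256. The three triplet branch roles are one
# parameter set; "branches" exist only as evaluation roles.

#' Encoder configuration
#'
#' @param n_bands Input bands per timestep (default 13).
#' @param hidden_dim LSTM hidden dimension H (default 128).
#' @param num_layers Stacked LSTM layers (default 1).
#' @param bidirectional Use a bidirectional encoder (default `TRUE`); the
#'   embedding dimension is `hidden_dim * (2 if bidirectional else 1)`.
#' @param dropout Inverted-dropout rate on the classification head's input
#'   during training (default 0, keeping runs deterministic).
#' @param n_classes Number of classes for the softmax head (default 13).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(n_bands = 13L, hidden_dim = 128L, num_layers = 1L,
                           bidirectional = TRUE, dropout = 0,
                           n_classes = 13L) {
  if (hidden_dim < 1) abort("hidden_dim must be >= 1")
  if (n_classes < 2) abort("n_classes must be >= 2")
  if (num_layers < 1) abort("num_layers must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(n_bands = as.integer(n_bands), hidden_dim = as.integer(hidden_dim),
         num_layers = as.integer(num_layers),
         bidirectional = isTRUE(bidirectional), dropout = as.numeric(dropout),
         n_classes = as.integer(n_classes)),
    class = "encoder_config")
}

# Walk the flat parameter layout: one entry per (layer, direction) unit
# with offsets of its W (in x 4H), U (H x 4H) and bias (4H) blocks.
param_units <- function(cfg) {
  H <- cfg$hidden_dim
  ndir <- if (cfg$bidirectional) 2L else 1L
  units <- list()
  off <- 0L
  for (l in seq_len(cfg$num_layers)) {
    in_l <- if (l == 1) cfg$n_bands else H * ndir
    for (d in seq_len(ndir)) {
      units[[length(units) + 1L]] <- list(
        in_dim = in_l, w_off = off, u_off = off + in_l * 4L * H,
        b_off = off + (in_l + H) * 4L * H)
      off <- off + (in_l + H) * 4L * H + 4L * H
    }
  }
  units
}

# forget-gate bias entries (gate blocks ordered input | forget | cell | output)
forget_bias_idx <- function(cfg) {
  H <- cfg$hidden_dim
  unlist(lapply(param_units(cfg), function(u) u$b_off + H + seq_len(H)))
}

random_orthogonal <- function(h) {
  qr_dec <- qr(matrix(rnorm(h * h), h))
  q <- qr.Q(qr_dec)
  # fix the sign convention so the distribution is Haar
  q %*% diag(sign(diag(qr.R(qr_dec))), h)
}

embedding_dim <- function(cfg) {
  cfg$hidden_dim * (if (cfg$bidirectional) 2L else 1L)
}

n_params <- function(cfg) {
  cpp_n_params(cfg$n_bands, cfg$hidden_dim, cfg$num_layers,
               cfg$bidirectional, cfg$n_classes)
}

#' Initialize a triplet LSTM model
#'
#' Input and head weights draw uniformly from `(-1/sqrt(H), 1/sqrt(H))`;
#' recurrent weights get one random orthogonal matrix per gate and
#' forget-gate biases start at 1 — the standard stabilizing choices for
#' recurrent networks. Uses the ambient R RNG (seed it, or pass `seed`,
#' for reproducible initialization).
#'
#' @param config An [encoder_config()].
#' @param seed Optional integer seed applied locally.
#' @param class_names Optional label names carried into reports.
#' @return An object of class `triplet_lstm` with elements `config`,
#'   `params` (flat numeric vector) and `class_names`.
#' @export
init_triplet_lstm <- function(config = encoder_config(), seed = NULL,
                              class_names = NULL) {
  draw <- function() {
    H <- config$hidden_dim
    k <- 1 / sqrt(H)
    params <- runif(n_params(config), -k, k)
    # recurrent blocks: one orthogonal H x H matrix per gate, the standard
    # stabilizing choice for recurrent weights
    for (u in param_units(config)) {
      for (g in 0:3) {
        params[u$u_off + g * H * H + seq_len(H * H)] <- random_orthogonal(H)
      }
    }
    params[forget_bias_idx(config)] <- 1
    params
  }
  params <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(class_names)) {
    class_names <- paste0("class_", seq_len(config$n_classes) - 1L)
  }
  structure(list(config = config, params = params, class_names = class_names),
            class = "triplet_lstm")
}

#' @export
print.triplet_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<triplet_lstm> %s%d-unit LSTM x%d layer(s), %d bands -> %d-d embedding -> %d classes (%s parameters)\n",
    if (cfg$bidirectional) "bidirectional " else "", cfg$hidden_dim,
    cfg$num_layers, cfg$n_bands, embedding_dim(cfg), cfg$n_classes,
    format(length(x$params), big.mark = ",")))
  invisible(x)
}

encode_array <- function(model, arr) {
  cfg <- model$config
  cpp_encode(arr, model$params, cfg$n_bands, cfg$hidden_dim, cfg$num_layers,
             cfg$bidirectional, cfg$n_classes)
}

#' Embed parcels with the trained (or untrained) encoder
#'
#' Deterministic inference-mode forward pass; dropout is never applied.
#'
#' @param model A `triplet_lstm` (or the `model` element of a fit).
#' @param df A standardized parcel tibble whose band count matches the model.
#' @return The tibble with an added `embedding` list-column of numeric
#'   vectors (length `hidden_dim * 2` for a bidirectional encoder).
#' @export
embed_parcels <- function(model, df) {
  model <- as_triplet_lstm(model)
  if (parcel_meta(df)$n_bands != model$config$n_bands) {
    abort(sprintf("data has %d bands but the model expects %d",
                  parcel_meta(df)$n_bands, model$config$n_bands))
  }
  emb <- encode_array(model, series_array(df))
  out <- df
  out$embedding <- lapply(seq_len(nrow(emb)), function(i) emb[i, ])
  out
}

#' Class probabilities from embeddings
#'
#' Applies the fully connected layer and the softmax
#' `sigma(z)(i) = exp(z_i) / sum_j exp(z_j)`; rows sum to 1 and the output
#' is invariant to adding a constant to all logits.
#'
#' @param model A `triplet_lstm`.
#' @param embeddings Numeric matrix (rows are samples) or a tibble from
#'   [embed_parcels()].
#' @return Probability matrix with one column per class.
#' @export
classify <- function(model, embeddings) {
  model <- as_triplet_lstm(model)
  if (is.data.frame(embeddings)) {
    embeddings <- do.call(rbind, embeddings$embedding)
  }
  if (!is.matrix(embeddings)) embeddings <- matrix(embeddings, nrow = 1)
  cfg <- model$config
  if (ncol(embeddings) != embedding_dim(cfg)) {
    abort(sprintf("embedding dimension %d does not match the model's %d",
                  ncol(embeddings), embedding_dim(cfg)))
  }
  probs <- cpp_classify(embeddings, model$params, cfg$n_bands, cfg$hidden_dim,
                        cfg$num_layers, cfg$bidirectional, cfg$n_classes)
  colnames(probs) <- model$class_names
  probs
}

#' Predict classes, probabilities or embeddings for parcels
#'
#' Argmax ties break toward the lower class index, deterministically.
#'
#' @param object A `triplet_lstm`.
#' @param newdata A standardized parcel tibble.
#' @param type `"class"` (0-based integer labels), `"prob"` or
#'   `"embedding"`.
#' @param ... Unused.
#' @return Integer vector, probability matrix, or embedding matrix.
#' @export
predict.triplet_lstm <- function(object, newdata,
                                 type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  emb <- encode_array(object, series_array(newdata))
  if (type == "embedding") return(emb)
  probs <- classify(object, emb)
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first") - 1L
}

as_triplet_lstm <- function(x) {
  if (inherits(x, "triplet_lstm_fit")) return(x$model)
  if (!inherits(x, "triplet_lstm")) abort("expected a triplet_lstm model or fit")
  x
}

#' Save a model checkpoint as versioned JSON
#'
#' Text format: a header (`format`, `version`), the encoder configuration,
#' the label map, and the flat parameter vector at full double precision.
#'
#' @param model A `triplet_lstm` or a fit (its best model is saved).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  model <- as_triplet_lstm(model)
  jsonlite::write_json(
    list(format = "tripletlstm-checkpoint", version = 1L,
         config = unclass(model$config), class_names = model$class_names,
         params = model$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path A file written by [save_checkpoint()].
#' @return A `triplet_lstm`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "tripletlstm-checkpoint")) {
    abort("not a tripletlstm checkpoint file")
  }
  if (x$version > 1L) abort("checkpoint version newer than this package supports")
  cfg <- do.call(encoder_config, x$config[c("n_bands", "hidden_dim",
                                            "num_layers", "bidirectional",
                                            "dropout", "n_classes")])
  structure(list(config = cfg, params = as.numeric(x$params),
                 class_names = x$class_names),
            class = "triplet_lstm")
}
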