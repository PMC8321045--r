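# Encoder contracts: determinism, weight sharing across branch roles,
# softmax behaviour, embedding dimension, gradient correctness, checkpoints.

test_that("embedding is deterministic and shared across branch roles", {
  df <- sim_split(80, seed = 51)
  model <- init_triplet_lstm(toy_encoder(), seed = 3)
  e1 <- predict(model, df, type = "embedding")
  e2 <- predict(model, df, type = "embedding")
  expect_identical(e1, e2)

  # one parameter set serves all three branch roles: feeding the same batch
  # as anchor and positive yields zero anchor-positive distance everywhere
  arr <- series_array(df[1:6, ])
  far <- series_array(df[7:12, ])
  cfg <- model$config
  st <- tripletlstm:::cpp_triplet_step(
    arr, arr, far, df$label[1:6], df$label[1:6], df$label[7:12],
    model$params, rep(1, 4), 1, 1, cfg$n_bands, cfg$hidden_dim,
    cfg$num_layers, cfg$bidirectional, cfg$n_classes, NULL)
  # D(a,p) = 0 for every triplet, so the mean hinge is mean(max(0, m - D(a,n)))
  ea <- tripletlstm:::encode_array(model, arr)
  en <- tripletlstm:::encode_array(model, far)
  d_an <- sqrt(rowSums((ea - en)^2))
  expect_equal(st$margin_loss, mean(pmax(0, 1 - d_an)), tolerance = 1e-12)
})

test_that("untrained embeddings are reproducible from a frozen seed", {
  df <- sim_split(20, seed = 52)
  m1 <- init_triplet_lstm(toy_encoder(), seed = 77)
  m2 <- init_triplet_lstm(toy_encoder(), seed = 77)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, df, type = "embedding"),
                   predict(m2, df, type = "embedding"))
})

test_that("softmax head normalizes, is shift-invariant, and matches hand values", {
  model <- init_triplet_lstm(toy_encoder(), seed = 1)
  set.seed(2)
  emb <- matrix(rnorm(5 * 16), 5)
  p <- classify(model, emb)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  # shift invariance: adding a constant to all logits changes nothing;
  # exercised through the FC bias, which shifts every logit equally only if
  # we alter all outputs, so check on the softmax math directly
  soft <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  z <- rnorm(7)
  expect_equal(soft(z), soft(z + 3.7), tolerance = 1e-12)
  # logits (0, ln 3) -> probabilities (0.25, 0.75)
  expect_equal(soft(c(0, log(3))), c(0.25, 0.75))

  # equal logits -> uniform probabilities: zero the FC block
  m0 <- model
  fc_len <- 16 * 4 + 4
  m0$params[(length(m0$params) - fc_len + 1):length(m0$params)] <- 0
  expect_equal(classify(m0, emb)[1, ], setNames(rep(0.25, 4), paste0("class_", 0:3)))

  expect_error(classify(model, matrix(rnorm(10), 2, 5)), "dimension")
})

test_that("default configuration yields a 256-dimensional embedding", {
  cfg <- encoder_config()
  expect_equal(cfg$hidden_dim, 128L)
  expect_true(cfg$bidirectional)
  expect_equal(tripletlstm:::embedding_dim(cfg), 256L)
  # and a unidirectional variant halves it
  expect_equal(tripletlstm:::embedding_dim(encoder_config(bidirectional = FALSE)),
               128L)
})

test_that("analytic gradients match finite differences for 1- and 2-layer encoders", {
  for (L in 1:2) {
    set.seed(40 + L)
    cfg <- toy_encoder(n_bands = 3, n_classes = 3, hidden_dim = 4, num_layers = L)
    mo <- init_triplet_lstm(cfg, seed = 7)
    N <- 2; Tn <- 5
    arrs <- lapply(1:3, function(i) array(rnorm(N * 3 * Tn), c(N, 3, Tn)))
    ya <- c(0L, 1L); yp <- c(0L, 1L); yn <- c(1L, 2L)
    w <- c(1.2, 0.8, 1.0)
    f <- function(p) tripletlstm:::cpp_triplet_step(
      arrs[[1]], arrs[[2]], arrs[[3]], ya, yp, yn, p, w, 0.7, 1.0,
      3L, 4L, L, TRUE, 3L, NULL)$total
    st <- tripletlstm:::cpp_triplet_step(
      arrs[[1]], arrs[[2]], arrs[[3]], ya, yp, yn, mo$params, w, 0.7, 1.0,
      3L, 4L, L, TRUE, 3L, NULL)
    h <- 1e-6
    for (j in sample(length(st$grad), 40)) {
      p1 <- mo$params; p1[j] <- p1[j] + h
      p2 <- mo$params; p2[j] <- p2[j] - h
      num <- (f(p1) - f(p2)) / (2 * h)
      expect_lt(abs(num - st$grad[j]) / max(1, abs(num)), 1e-6)
    }
  }
})

test_that("band-count mismatches are rejected", {
  df <- sim_split(20, seed = 53)
  model <- init_triplet_lstm(encoder_config(n_bands = 7, n_classes = 4), seed = 1)
  expect_error(embed_parcels(model, df), "bands")
})

test_that("checkpoints round-trip through versioned JSON", {
  df <- sim_split(30, seed = 54)
  model <- init_triplet_lstm(toy_encoder(), seed = 13,
                             class_names = paste0("crop", 0:3))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  header <- jsonlite::read_json(path)
  expect_identical(header$format, "tripletlstm-checkpoint")
  expect_identical(header$version, 1L)

  back <- load_checkpoint(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_identical(back$class_names, model$class_names)
  expect_identical(unclass(back$config), unclass(model$config))
  expect_equal(predict(back, df, type = "prob"),
               predict(model, df, type = "prob"), tolerance = 1e-12)
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), other, auto_unbox = TRUE)
  expect_error(load_checkpoint(other), "not a tripletlstm checkpoint")
})
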