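# The optimization loop: reproducibility, early stopping, gradient flow,
# learning on separable data, and multirun aggregation.

test_that("identical seeds give identical runs, different seeds differ", {
  df <- sim_split(240, seed = 71)
  tc <- train_config(setup = "setup2", max_epochs = 3, patience = 5,
                     batch_size = 32, seed = 9)
  f1 <- train_triplet_lstm(df, toy_encoder(), tc)
  f2 <- train_triplet_lstm(df, toy_encoder(), tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  tc$seed <- 10L
  f3 <- train_triplet_lstm(df, toy_encoder(), tc)
  expect_false(identical(f1$history, f3$history))
})

test_that("early stopping returns the checkpoint with the best validation accuracy", {
  df <- sim_split(240, seed = 72)
  tc <- train_config(setup = "setup1", max_epochs = 6, patience = 2,
                     batch_size = 32, seed = 4)
  fit <- train_triplet_lstm(df, toy_encoder(), tc)
  h <- tidy(fit)
  expect_equal(fit$best_val_accuracy, max(h$val_accuracy))
  expect_equal(fit$best_epoch, which.max(h$val_accuracy))
  # stopping rule: no more than patience epochs beyond the best one
  expect_lte(nrow(h), fit$best_epoch + tc$patience)
  # the returned model reproduces the recorded best accuracy
  val <- df[df$split == "validation", ]
  acc <- mean(predict(fit$model, val, type = "class") == val$label)
  expect_equal(acc, fit$best_val_accuracy)
})

test_that("every parameter receives gradient on a generic batch", {
  df <- sim_split(120, seed = 73)
  model <- init_triplet_lstm(toy_encoder(), seed = 2)
  tr <- sample_triplets(df, 16, setup = "setup2", seed = 3)
  train_rows <- df
  arr <- series_array(train_rows)
  cfg <- model$config
  st <- tripletlstm:::cpp_triplet_step(
    arr[tr$anchor, , , drop = FALSE], arr[tr$positive, , , drop = FALSE],
    arr[tr$negative, , , drop = FALSE],
    df$label[tr$anchor], df$label[tr$positive], df$label[tr$negative],
    model$params, rep(1, 4), 1, 1, cfg$n_bands, cfg$hidden_dim,
    cfg$num_layers, cfg$bidirectional, cfg$n_classes, NULL)
  expect_true(all(st$grad != 0))
})

test_that("training on separable synthetic data reaches high validation accuracy", {
  df <- sim_split(600, seed = 74, region_shift_scale = 0.01, noise_sd = 0.01)
  tc <- train_config(setup = "setup1", max_epochs = 15, patience = 15,
                     batch_size = 32, seed = 1)
  fit <- train_triplet_lstm(df, toy_encoder(hidden_dim = 16), tc)
  expect_gte(fit$best_val_accuracy, 0.85)
})

test_that("class weighting can be disabled and then all weights are one", {
  df <- sim_split(160, seed = 75)
  tc <- train_config(setup = "setup2", max_epochs = 1, patience = 1,
                     batch_size = 32, seed = 2, weighting = "none")
  fit <- train_triplet_lstm(df, toy_encoder(), tc)
  expect_null(fit$class_weights)
  tc2 <- train_config(setup = "setup2", max_epochs = 1, patience = 1,
                      batch_size = 32, seed = 2)
  fit2 <- train_triplet_lstm(df, toy_encoder(), tc2)
  expect_s3_class(fit2$class_weights, "tbl_df")
  expect_equal(fit2$class_weights$weight * fit2$class_weights$frequency,
               rep(median(fit2$class_weights$frequency), 4))
})

test_that("multirun aggregates per-run metrics into exact means and sds", {
  df <- sim_split(200, seed = 76)
  tc <- train_config(setup = "setup2", max_epochs = 2, patience = 2,
                     batch_size = 32, seed = 5)
  mr <- multirun(df, toy_encoder(), tc, n_runs = 3)
  per_run <- tidy(mr)
  expect_equal(nrow(per_run), 3)
  expect_equal(sort(per_run$seed), c(5L, 6L, 7L))
  # arithmetic oracle on a stored metric
  oa <- per_run$overall_accuracy
  s <- mr$summary
  expect_equal(s$mean[s$metric == "overall_accuracy"], mean(oa))
  expect_equal(s$sd[s$metric == "overall_accuracy"], stats::sd(oa))

  mr1 <- multirun(df, toy_encoder(), tc, n_runs = 1)
  expect_equal(nrow(tidy(mr1)), 1)
  expect_true(all(mr1$summary$sd == 0))
  expect_equal(tidy(mr1)$overall_accuracy[1],
               mr1$summary$mean[mr1$summary$metric == "overall_accuracy"])

  expect_error(multirun(df, toy_encoder(), tc, n_runs = 2, seeds = c(1L, 1L)),
               "distinct")
})

test_that("dropout keeps training runnable and inference deterministic", {
  df <- sim_split(160, seed = 77)
  ecfg <- encoder_config(n_bands = 4, n_classes = 4, hidden_dim = 8,
                         dropout = 0.3)
  tc <- train_config(setup = "setup2", max_epochs = 2, patience = 2,
                     batch_size = 32, seed = 3)
  fit <- train_triplet_lstm(df, ecfg, tc)
  expect_true(all(is.finite(fit$history$total)))
  p1 <- predict(fit$model, df[1:5, ], type = "prob")
  p2 <- predict(fit$model, df[1:5, ], type = "prob")
  expect_identical(p1, p2)
})
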