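# Metrics, confusion matrices, and embedding separation diagnostics.

random_confusion <- function(k, n = 200) {
  truth <- sample(0:(k - 1), n, replace = TRUE)
  pred <- ifelse(runif(n) < 0.6, truth, sample(0:(k - 1), n, replace = TRUE))
  list(truth = truth, pred = pred)
}

test_that("perfect predictions give OA, kappa and all macro metrics of 1", {
  truth <- rep(0:3, times = c(10, 5, 3, 2))
  rep <- metrics_report(truth, truth, 4)
  m <- glance(rep)
  expect_equal(m$overall_accuracy, 1)
  expect_equal(m$kappa, 1)
  expect_equal(m$mean_f1, 1)
  expect_equal(m$mean_precision, 1)
  expect_equal(m$mean_recall, 1)
})

test_that("a constant predictor on a balanced 2-class set has OA 0.5, kappa 0", {
  truth <- rep(c(0L, 1L), each = 25)
  pred <- rep(0L, 50)
  m <- glance(metrics_report(truth, pred, 2))
  expect_equal(m$overall_accuracy, 0.5)
  expect_equal(m$kappa, 0)
})

test_that("metrics match the textbook-formula oracle on random tables", {
  set.seed(61)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    rc <- random_confusion(k)
    rep <- metrics_report(rc$truth, rc$pred, k)
    want <- oracle_metrics(rep$confusion$raw)
    m <- glance(rep)
    expect_equal(m$overall_accuracy, want$oa, tolerance = 1e-9)
    expect_equal(m$kappa, want$kappa, tolerance = 1e-9)
    expect_equal(m$mean_f1, want$mean_f1, tolerance = 1e-9)
    expect_equal(m$mean_precision, want$mean_precision, tolerance = 1e-9)
    expect_equal(m$mean_recall, want$mean_recall, tolerance = 1e-9)
    # kappa identity against independently recomputed chance agreement
    cm <- rep$confusion$raw
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    expect_equal(m$kappa, (m$overall_accuracy - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("confusion pair normalizations and count invariants hold", {
  set.seed(62)
  rc <- random_confusion(5, 300)
  cm <- confusion_pair(rc$truth, rc$pred, 5)
  expect_equal(sum(cm$raw), 300)
  expect_true(all(cm$raw >= 0))
  nonzero_cols <- colSums(cm$raw) > 0
  expect_equal(colSums(cm$precision)[nonzero_cols],
               rep(1, sum(nonzero_cols)) |>
                 setNames(colnames(cm$raw)[nonzero_cols]), tolerance = 1e-9)
  nonzero_rows <- rowSums(cm$raw) > 0
  expect_equal(rowSums(cm$recall)[nonzero_rows],
               rep(1, sum(nonzero_rows)) |>
                 setNames(rownames(cm$raw)[nonzero_rows]), tolerance = 1e-9)

  # permuting samples leaves everything unchanged
  perm <- sample(length(rc$truth))
  cm2 <- confusion_pair(rc$truth[perm], rc$pred[perm], 5)
  expect_identical(cm$raw, cm2$raw)

  # raw counts do not depend on class display names
  cm3 <- confusion_pair(rc$truth, rc$pred, 5, class_names = letters[1:5])
  expect_equal(unname(cm3$raw), unname(cm$raw))
})

test_that("macro averages run over all declared classes, empty ones as zero", {
  # class 2 never occurs and is never predicted
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 0L, 1L, 0L)
  rep <- metrics_report(truth, pred, 3)
  pc <- tidy(rep)
  expect_equal(pc$precision[3], 0)
  expect_equal(pc$recall[3], 0)
  expect_equal(glance(rep)$mean_recall, mean(c(1, 0.5, 0)))
})

test_that("embedding separation matches a brute-force pairwise computation", {
  # two point-mass classes at distance d
  emb <- rbind(matrix(0, 4, 3), matrix(2, 4, 3)) # centroid distance 2*sqrt(3)
  labels <- rep(0:1, each = 4)
  s <- embedding_separation(emb, labels)
  expect_equal(s$within, 0)
  expect_equal(s$between, 2 * sqrt(3))
  expect_equal(s$ratio, Inf)

  set.seed(63)
  emb <- matrix(rnorm(200 * 4), 200)
  labels <- sample(0:3, 200, replace = TRUE)
  s <- embedding_separation(emb, labels)
  # O(n^2) oracle
  wd <- c(); for (i in 1:199) for (j in (i + 1):200) {
    if (labels[i] == labels[j]) wd <- c(wd, sqrt(sum((emb[i, ] - emb[j, ])^2)))
  }
  cents <- t(sapply(0:3, function(k) colMeans(emb[labels == k, , drop = FALSE])))
  bd <- c(); for (i in 1:3) for (j in (i + 1):4) {
    bd <- c(bd, sqrt(sum((cents[i, ] - cents[j, ])^2)))
  }
  expect_equal(s$within, mean(wd), tolerance = 1e-9)
  expect_equal(s$between, mean(bd), tolerance = 1e-9)
  expect_equal(s$ratio, mean(bd) / mean(wd), tolerance = 1e-9)

  expect_error(embedding_separation(emb, rep(0L, 200)), "2 classes")
})

test_that("evaluate_model refuses empty sample lists and reports n_samples", {
  df <- sim_split(60, seed = 64)
  model <- init_triplet_lstm(toy_encoder(), seed = 5)
  expect_error(evaluate_model(model, df[0, ]), "empty")
  rep <- evaluate_model(model, df[df$split == "test", ])
  expect_equal(glance(rep)$n_samples, sum(df$split == "test"))
})

test_that("metrics writer emits versioned JSON and confusion CSVs", {
  df <- sim_split(60, seed = 65)
  model <- init_triplet_lstm(toy_encoder(), seed = 6)
  rep <- evaluate_model(model, df[df$split == "test", ])
  json <- withr::local_tempfile(fileext = ".json")
  prefix <- withr::local_tempfile()
  write_metrics(rep, json, prefix)
  x <- jsonlite::read_json(json)
  expect_identical(x$format, "tripletlstm-metrics")
  raw <- readr::read_csv(paste0(prefix, "_raw.csv"),
                         col_types = readr::cols())
  expect_equal(nrow(raw), 4)
  expect_true("truth" %in% names(raw))
})
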