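# The loss components against hand calculations and naive scalar oracles.

test_that("inverse median frequency weights follow w_k = median(g) / g(k)", {
  # frequencies (0.5, 0.3, 0.2) -> weights (0.6, 1.0, 1.5)
  labels <- rep(c(0L, 1L, 2L), times = c(50, 30, 20))
  w <- class_weights(labels, 3)
  expect_equal(w$weight, c(0.6, 1.0, 1.5))
  expect_equal(w$frequency, c(0.5, 0.3, 0.2))

  # balanced classes: all weights exactly 1
  wb <- class_weights(rep(0:4, each = 7), 5)
  expect_identical(wb$weight, rep(1, 5))

  # the identity w_k * g(k) = median(g) holds exactly, and the rarest class
  # gets the largest weight, for arbitrary multisets
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    counts <- sample(1:40, n, replace = TRUE)
    labels <- rep(seq_len(n) - 1L, times = counts)
    w <- class_weights(labels, n)
    expect_equal(w$weight * w$frequency, rep(median(w$frequency), n))
    expect_equal(which.max(w$weight), which.min(w$count))
  }

  expect_error(class_weights(c(0L, 0L, 2L), 3), "absent",
               class = "tripletlstm_weight_error")
})

test_that("weighted cross-entropy matches hand values and is linear in the weight", {
  # p_true = 1 -> 0 loss
  expect_equal(weighted_cross_entropy(c(1, 0), 0L), 0)
  # p_true = 0.5, w = 1 -> ln 2
  expect_equal(weighted_cross_entropy(c(0.5, 0.5), 0L), log(2))
  # doubling the true class weight doubles the loss
  l1 <- weighted_cross_entropy(c(0.3, 0.7), 1L, c(1, 2))
  l2 <- weighted_cross_entropy(c(0.3, 0.7), 1L, c(1, 4))
  expect_equal(l2, 2 * l1)
  # log clamp keeps confident mistakes finite
  expect_true(is.finite(weighted_cross_entropy(c(0, 1), 0L)))
  # one-hot matrix input; malformed rows rejected
  y <- rbind(c(0, 1), c(1, 0))
  p <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  expect_equal(weighted_cross_entropy(p, y), c(-log(0.8), -log(0.6)))
  expect_error(weighted_cross_entropy(p, rbind(c(1, 1), c(1, 0))), "one-hot")
})

test_that("triplet loss matches Euclidean hinge hand values", {
  # D(a,p) = 1, D(a,n) = 0.5, m = 1 -> 1.5
  e_a <- c(0, 0); e_p <- c(1, 0); e_n <- c(0, 0.5)
  expect_equal(triplet_loss(e_a, e_p, e_n, margin = 1), 1.5)
  # anchor == positive and far negative: hinge inactive
  expect_equal(triplet_loss(c(0, 0), c(0, 0), c(5, 0), margin = 1), 0)
  # m = 0 and identical positive/negative embeddings cancel
  expect_equal(triplet_loss(c(1, 2), c(3, 4), c(3, 4), margin = 0), 0)
  # batch form is the mean of per-triplet hinges
  ea <- rbind(c(0, 0), c(0, 0)); ep <- rbind(c(1, 0), c(0, 0))
  en <- rbind(c(0, 0.5), c(5, 0))
  expect_equal(triplet_loss(ea, ep, en, margin = 1), mean(c(1.5, 0)))
  expect_equal(triplet_loss(ea, ep, en, margin = 1, reduce = "none"), c(1.5, 0))
  expect_error(triplet_loss(c(1, 2), c(1, 2, 3), c(0, 0)), "dimension")
})

test_that("triplet loss is invariant to a rigid common translation", {
  set.seed(7)
  for (i in 1:10) {
    ea <- matrix(rnorm(12), 3); ep <- matrix(rnorm(12), 3); en <- matrix(rnorm(12), 3)
    shift <- matrix(rnorm(4), 3, 4, byrow = TRUE)
    expect_equal(triplet_loss(ea, ep, en),
                 triplet_loss(ea + shift, ep + shift, en + shift))
  }
})

test_that("total loss equals the component sum and reduces at lambda = 0", {
  set.seed(11)
  mk_probs <- function(n, k) {
    z <- matrix(rexp(n * k), n)
    z / rowSums(z)
  }
  probs <- list(anchor = mk_probs(4, 3), positive = mk_probs(4, 3),
                negative = mk_probs(4, 3))
  labels <- list(anchor = sample(0:2, 4, TRUE), positive = sample(0:2, 4, TRUE),
                 negative = sample(0:2, 4, TRUE))
  emb <- list(anchor = matrix(rnorm(8), 4), positive = matrix(rnorm(8), 4),
              negative = matrix(rnorm(8), 4))
  w <- c(1.5, 1, 0.5)

  lt <- total_loss(probs, labels, emb, w, margin = 0.7, lambda = 2)
  ce_expect <- sum(sapply(c("anchor", "positive", "negative"), function(r)
    mean(sapply(seq_len(4), function(i)
      oracle_cross_entropy(probs[[r]][i, ], labels[[r]][i], w)))))
  lm_expect <- mean(sapply(seq_len(4), function(i)
    oracle_triplet_loss(emb$anchor[i, ], emb$positive[i, ], emb$negative[i, ], 0.7)))
  expect_equal(as.numeric(lt), ce_expect + 2 * lm_expect, tolerance = 1e-12)

  l0 <- total_loss(probs, labels, emb, w, margin = 0.7, lambda = 0)
  expect_equal(as.numeric(l0), ce_expect, tolerance = 1e-12)

  # non-decreasing in lambda while the hinge is active
  l1 <- total_loss(probs, labels, emb, w, margin = 0.7, lambda = 1)
  expect_gte(as.numeric(lt), as.numeric(l1))

  # perfect classification with inactive hinge gives exactly zero
  sure <- list(anchor = diag(3)[c(1, 2), ], positive = diag(3)[c(1, 2), ],
               negative = diag(3)[c(2, 3), ])
  lab <- list(anchor = c(0L, 1L), positive = c(0L, 1L), negative = c(1L, 2L))
  e0 <- matrix(0, 2, 2)
  far <- matrix(c(10, 0, 10, 0), 2, byrow = TRUE)
  z <- total_loss(sure, lab, list(anchor = e0, positive = e0, negative = far),
                  weights = NULL, margin = 1, lambda = 1)
  expect_equal(as.numeric(z), 0)
})

test_that("all loss components are non-negative on random inputs", {
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    z <- rexp(k); p <- z / sum(z)
    expect_gte(weighted_cross_entropy(p, sample(0:(k - 1), 1), runif(k, 0.1, 3)), 0)
    expect_gte(triplet_loss(rnorm(4), rnorm(4), rnorm(4), margin = runif(1, 0, 2)), 0)
  }
})
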