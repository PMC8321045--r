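# Triplet construction under the two selection protocols.
#
# setup-1 (region-aware): anchor and negative share a training region, the
# positive comes from a different training region — triplets thus pair hard
# positives (same class, other region) with hard negatives (other class,
# same region).
# setup-2 (naive): positive same-class, negative different-class, both drawn
# from the whole training set with no region constraint.

#' Sample training triplets
#'
#' Draws `count` (anchor, positive, negative) index triples from the training
#' rows of `df`. Anchors are drawn uniformly over the training set, with
#' replacement. Under `"setup1"` the negative is drawn from the anchor's
#' region among other-class samples and the positive from the anchor's class
#' in the other training region(s); under `"setup2"` there is no region
#' constraint. Positives exclude the anchor itself whenever the class has
#' another eligible sample.
#'
#' @param df A parcel tibble; if it carries a `split` column only
#'   `split == "train"` rows are used, otherwise all rows.
#' @param count Number of triplets.
#' @param setup `"setup1"` (region-aware) or `"setup2"` (naive).
#' @param seed Optional integer seed applied locally; by default draws
#'   consume the ambient RNG stream.
#' @return A tibble with integer columns `anchor`, `positive`, `negative`
#'   (row indices into `df`) and a `setup` column.
#' @export
sample_triplets <- function(df, count, setup = c("setup1", "setup2"),
                            seed = NULL) {
  setup <- match.arg(setup)
  if (count < 1) abort("count must be >= 1")
  idx <- if ("split" %in% names(df)) which(df$split == "train") else seq_len(nrow(df))
  if (length(idx) == 0) abort("no training samples available")
  labels <- df$label[idx]
  regions <- df$region[idx]
  check_triplet_feasible(labels, regions, setup)

  draw <- function() {
    pool_by_class <- split(idx, labels)
    if (setup == "setup1") {
      # pools keyed by class x region
      pos_pool <- list()  # same class, OTHER region
      neg_pool <- list()  # same region, OTHER class
      for (k in unique(labels)) {
        for (r in unique(regions)) {
          pos_pool[[paste(k, r)]] <- idx[labels == k & regions != r]
          neg_pool[[paste(k, r)]] <- idx[labels != k & regions == r]
        }
      }
    }
    anchor <- idx[sample.int(length(idx), count, replace = TRUE)]
    positive <- integer(count)
    negative <- integer(count)
    for (i in seq_len(count)) {
      a <- anchor[i]
      k <- df$label[a]
      if (setup == "setup1") {
        key <- paste(k, df$region[a])
        pp <- pos_pool[[key]]
        np <- neg_pool[[key]]
      } else {
        pp <- setdiff(pool_by_class[[as.character(k)]], a)
        if (length(pp) == 0) pp <- a # degenerate singleton class
        np <- idx[labels != k]
      }
      positive[i] <- pp[sample.int(length(pp), 1)]
      negative[i] <- np[sample.int(length(np), 1)]
    }
    tibble(anchor = anchor, positive = positive, negative = negative,
           setup = setup)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_triplet_feasible <- function(labels, regions, setup) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort("triplet sampling needs at least 2 classes in the training set",
          class = "tripletlstm_sampling_error")
  }
  if (setup == "setup1") {
    if (length(unique(regions)) < 2) {
      abort("setup-1 needs at least 2 training regions",
            class = "tripletlstm_sampling_error")
    }
    nreg <- vapply(classes, function(k) length(unique(regions[labels == k])),
                   integer(1))
    if (any(nreg < 2)) {
      abort(paste0("setup-1 infeasible: class(es) present in a single region: ",
                   paste(classes[nreg < 2], collapse = ", ")),
            class = "tripletlstm_sampling_error")
    }
    # a negative must exist within each occupied region
    for (r in unique(regions)) {
      if (length(unique(labels[regions == r])) < 2) {
        abort(sprintf("setup-1 infeasible: region %s holds a single class", r),
              class = "tripletlstm_sampling_error")
      }
    }
  }
  invisible(TRUE)
}

#' Verify triplet constraints
#'
#' Predicate used by the tests and the training loop's assertions: every
#' triplet must pair same-class anchor/positive and different-class negative;
#' setup-1 triplets must additionally share the anchor's region with the
#' negative and place the positive in a different region.
#'
#' @param triplets Output of [sample_triplets()].
#' @param df The parcel tibble the indices refer to.
#' @return Logical vector, one entry per triplet.
#' @export
triplet_constraints_ok <- function(triplets, df) {
  ok <- df$label[triplets$anchor] == df$label[triplets$positive] &
    df$label[triplets$anchor] != df$label[triplets$negative]
  s1 <- triplets$setup == "setup1"
  ok[s1] <- ok[s1] &
    df$region[triplets$anchor[s1]] == df$region[triplets$negative[s1]] &
    df$region[triplets$anchor[s1]] != df$region[triplets$positive[s1]]
  ok
}

#' Chunk triplets into batches
#'
#' Order-preserving chunking; the last batch may be short.
#'
#' @param triplets A triplet tibble.
#' @param batch_size Maximum triplets per batch (>= 1).
#' @return A list of triplet tibbles.
#' @export
triplet_batches <- function(triplets, batch_size) {
  if (batch_size < 1) abort("batch_size must be >= 1")
  n <- nrow(triplets)
  starts <- seq(1, n, by = batch_size)
  lapply(starts, function(s) triplets[s:min(s + batch_size - 1, n), ])
}
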