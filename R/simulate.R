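# Seeded crop-phenology simulator.
#
# Emulates the statistical structure the method assumes: 13 crop classes with
# smooth class-specific seasonal reflectance curves over 13 bands, 4 regions
# whose samples share a class profile up to a smooth regional shift, strong
# class imbalance, variable raw sequence lengths, and additive observation
# noise. Seasonal curves use the canonical double-logistic vegetation
# phenology form.

#' Configuration of the synthetic parcel generator
#'
#' The defaults mirror the reference dataset's structure: 13 classes over 13
#' bands and 4 regions, class proportions with three dominant classes
#' (temporary meadows, corn, permanent meadows) and rare classes below 1%
#' (orchards, protein crops), and a confusable class group
#' (fodder / permanent meadows / temporary meadows) whose profiles differ
#' only by small offsets.
#'
#' @param n_classes,n_regions,n_bands Structure counts.
#' @param t_raw_range Inclusive range of raw sequence lengths, later
#'   standardized to 45.
#' @param class_proportions Named numeric vector summing to 1; default is the
#'   imbalanced crop mixture described above (only for `n_classes = 13`;
#'   other class counts get a geometric imbalance).
#' @param region_shift_scale Magnitude (reflectance units) of the smooth
#'   per-region, per-class profile perturbation; this is the intra-class
#'   inter-region variation that region-aware triplet mining exploits.
#' @param noise_sd Standard deviation of additive Gaussian observation noise,
#'   clamped below at 0 so reflectances stay non-negative.
#' @param confusable_groups List of integer vectors of 0-based class labels
#'   sharing near-identical profiles.
#' @param seed Integer; fully determines the generator output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 13L, n_regions = 4L, n_bands = 13L,
                             t_raw_range = c(38L, 52L),
                             class_proportions = NULL,
                             region_shift_scale = 0.05,
                             noise_sd = 0.02,
                             confusable_groups = NULL,
                             seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.null(class_proportions)) {
    if (n_classes == 13L) {
      class_proportions <- c(
        barley = 0.050, wheat = 0.120, corn = 0.200, fodder = 0.030,
        fallow = 0.015, miscellaneous = 0.085, orchards = 0.005,
        cereals = 0.025, perm_meadows = 0.165, protein_crops = 0.005,
        rapeseed = 0.020, temp_meadows = 0.240, vegetables = 0.040)
    } else {
      p <- 0.7^seq_len(n_classes)
      class_proportions <- setNames(p / sum(p),
                                    paste0("class_", seq_len(n_classes) - 1L))
    }
  }
  if (length(class_proportions) != n_classes) {
    abort("class_proportions must have one entry per class")
  }
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("class_proportions must sum to 1")
  }
  if (is.null(confusable_groups)) {
    confusable_groups <- if (n_classes == 13L) list(c(3L, 8L, 11L)) else list()
  }
  for (g in confusable_groups) {
    if (any(g < 0 | g >= n_classes)) abort("confusable group labels out of range")
  }
  if (n_classes < 1 || n_regions < 1 || n_bands < 1) abort("counts must be >= 1")
  if (region_shift_scale < 0 || noise_sd < 0) abort("scales must be >= 0")
  structure(
    list(n_classes = n_classes, n_regions = as.integer(n_regions),
         n_bands = as.integer(n_bands),
         t_raw_range = as.integer(t_raw_range),
         class_proportions = class_proportions,
         region_shift_scale = region_shift_scale, noise_sd = noise_sd,
         confusable_groups = confusable_groups, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Double-logistic seasonal curve
#'
#' `baseline + amplitude * (1/(1+exp(-(t - peak + plateau)/rise)) -
#'  1/(1+exp(-(t - peak - plateau)/fall)))`: the standard smooth green-up /
#' senescence form for vegetation phenology. With `amplitude = 0` the curve
#' is flat at `baseline`.
#'
#' @param t Time (in 45-step season units).
#' @param baseline,amplitude Reflectance offset and seasonal amplitude
#'   (negative amplitudes model absorption features).
#' @param peak Center of the growing season.
#' @param plateau Half-width of the plateau between green-up and senescence.
#' @param rise,fall Green-up and senescence time constants (must be > 0).
#' @return Numeric vector of reflectances.
#' @export
double_logistic <- function(t, baseline, amplitude, peak, plateau, rise, fall) {
  if (any(rise <= 0) || any(fall <= 0)) abort("rise and fall widths must be > 0")
  baseline + amplitude * (1 / (1 + exp(-(t - peak + plateau) / rise)) -
                          1 / (1 + exp(-(t - peak - plateau) / fall)))
}

#' Draw per-class, per-band phenology profiles
#'
#' One double-logistic parameter set per class (seasonal shape) with per-band
#' baselines and amplitudes. Two visible "absorption" bands get negative
#' amplitudes bounded by the baseline so profiles stay non-negative. Classes
#' in a confusable group share the group leader's parameters up to small
#' offsets, reproducing the meadows/fodder confusion structure of real crop
#' maps.
#'
#' @param config A [synthetic_config()].
#' @return A tibble of class `phenology_profiles` with one row per
#'   (class, band): columns `class`, `band`, `baseline`, `amplitude`,
#'   `peak`, `plateau`, `rise`, `fall`.
#' @export
phenology_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$n_classes; Bn <- config$n_bands
  absorb <- intersect(c(3L, 4L), seq_len(Bn)) # red-region absorption bands
  withr::with_seed(config$seed, {
    shape <- tibble(
      class = seq_len(K) - 1L,
      peak = runif(K, 12, 32),
      plateau = runif(K, 3, 10),
      rise = runif(K, 1.5, 4.5),
      fall = runif(K, 1.5, 4.5)
    )
    bands <- purrr::map_dfr(seq_len(K) - 1L, function(k) {
      baseline <- runif(Bn, 0.03, 0.12)
      amplitude <- runif(Bn, 0.08, 0.35)
      amplitude[absorb] <- -runif(length(absorb), 0.2, 0.8) * baseline[absorb]
      tibble(class = k, band = seq_len(Bn), baseline = baseline,
             amplitude = amplitude)
    })
    prof <- dplyr::left_join(bands, shape, by = "class")
    # confusable groups: members track the leader up to small offsets
    for (g in config$confusable_groups) {
      lead <- g[1]
      for (k in g[-1]) {
        i <- prof$class == k
        j <- prof$class == lead
        prof$baseline[i] <- prof$baseline[j] + runif(Bn, -0.012, 0.012)
        prof$amplitude[i] <- prof$amplitude[j] * (1 + runif(Bn, -0.10, 0.10))
        prof$peak[i] <- prof$peak[j] + runif(1, -2, 2)
        prof$plateau[i] <- prof$plateau[j] * (1 + runif(1, -0.05, 0.05))
        prof$rise[i] <- prof$rise[j]
        prof$fall[i] <- prof$fall[j]
      }
    }
    class(prof) <- c("phenology_profiles", class(prof))
    prof
  })
}

# Smooth regional perturbation coefficients. Regional effects are mostly
# climate-driven and therefore common to all crops of a region (timing and
# magnitude of the season); a smaller class-specific interaction is added on
# top. Five coefficients per curve: constant offset, two harmonic
# amplitudes, two phases. Each curve is normalized to unit root-mean-square
# over the season so that region_shift_scale states the realized
# perturbation magnitude exactly, for every region and band.
region_shift_coefs <- function(config) {
  R <- config$n_regions; K <- config$n_classes; Bn <- config$n_bands
  draw <- function(m) {
    c0 <- rnorm(m, 0, 0.5); c1 <- rnorm(m); c2 <- rnorm(m, 0, 0.5)
    # RMS over t of c0 + c1 sin(u + p1) + 0.5 c2 sin(2u + p2)
    rms <- sqrt(c0^2 + 0.5 * c1^2 + 0.125 * c2^2)
    array(c(c0 / rms, c1 / rms, c2 / rms,
            runif(m, 0, 2 * pi), runif(m, 0, 2 * pi)), dim = c(m, 5))
  }
  withr::with_seed(config$seed + 1L, {
    list(common = array(draw(R * Bn), dim = c(R, Bn, 5)),
         interaction = array(draw(R * K * Bn), dim = c(R, K, Bn, 5)))
  })
}

shift_curve <- function(cf, t) {
  # cf: B x 5 coefficient matrix -> T x B smooth curve with O(1) magnitude
  Bn <- nrow(cf)
  u <- t / 44 * 2 * pi
  s1 <- sin(outer(u, rep(1, Bn)) + outer(rep(1, length(t)), cf[, 4]))
  s2 <- sin(outer(2 * u, rep(1, Bn)) + outer(rep(1, length(t)), cf[, 5]))
  outer(rep(1, length(t)), cf[, 1]) +
    sweep(s1, 2, cf[, 2], `*`) + 0.5 * sweep(s2, 2, cf[, 3], `*`)
}

profile_matrix <- function(prof_class, t) {
  # T x B curve for one class evaluated at times t (45-step units)
  shape <- double_logistic(t, 0, 1, prof_class$peak[1], prof_class$plateau[1],
                           prof_class$rise[1], prof_class$fall[1])
  outer(rep(1, length(t)), prof_class$baseline) +
    outer(shape, prof_class$amplitude)
}

region_shift_matrix <- function(coefs, region, class0, t, scale) {
  # T x B perturbation for one (region, class) cell: common regional effect
  # plus a 0.3-weighted class-specific interaction
  common <- shift_curve(matrix(coefs$common[region, , ],
                               ncol = 5), t)
  inter <- shift_curve(matrix(coefs$interaction[region, class0 + 1, , ],
                              ncol = 5), t)
  scale * (common + 0.3 * inter)
}

#' Simulate a labeled multi-region parcel dataset
#'
#' Draws class labels from the configured (imbalanced) mixture, assigns
#' regions to each class in a balanced random rotation — every region carries
#' every crop type, as in the reference dataset — and builds each sample as
#' class profile + regional smooth shift + i.i.d. Gaussian noise clamped at
#' zero. Raw lengths vary over `t_raw_range`; curves are evaluated on the
#' native 45-step season clock regardless of length. Output is fully
#' determined by `config$seed`.
#'
#' @param n Number of parcels.
#' @param config A [synthetic_config()].
#' @return A parcel tibble (see [parcel_tibble()]).
#' @export
simulate_parcels <- function(n, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  prof <- phenology_profiles(config)
  coefs <- region_shift_coefs(config)
  K <- config$n_classes
  regions <- sprintf("FRH%02d", seq_len(config$n_regions))
  prof_by_class <- split(prof, prof$class)

  withr::with_seed(config$seed + 2L, {
    label <- sample.int(K, n, replace = TRUE,
                        prob = config$class_proportions) - 1L
    region <- character(n)
    for (k in seq_len(K) - 1L) {
      idx <- which(label == k)
      if (length(idx) > 0) {
        # balanced random rotation over regions within each class
        region[idx] <- sample(rep_len(sample(regions), length(idx)))
      }
    }
    lens <- seq(config$t_raw_range[1], config$t_raw_range[2])
    t_raw <- lens[sample.int(length(lens), n, replace = TRUE)]
    series <- vector("list", n)
    for (i in seq_len(n)) {
      tt <- seq(0, 44, length.out = t_raw[i])
      m <- profile_matrix(prof_by_class[[as.character(label[i])]], tt) +
        region_shift_matrix(coefs, match(region[i], regions), label[i], tt,
                            config$region_shift_scale)
      if (config$noise_sd > 0) {
        m <- m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m), ncol(m))
      }
      series[[i]] <- pmax(m, 0)
    }
    parcel_tibble(
      parcel_id = sprintf("SYN%06d", seq_len(n)),
      region = region, label = label, series = series,
      n_classes = K, class_names = names(config$class_proportions))
  })
}

#' @export
autoplot.phenology_profiles <- function(object, t = seq(0, 44, by = 0.5), ...) {
  curves <- tidyr::crossing(object, t = t) |>
    dplyr::mutate(reflectance = double_logistic(
      .data$t, .data$baseline, .data$amplitude, .data$peak, .data$plateau,
      .data$rise, .data$fall))
  ggplot2::ggplot(curves, ggplot2::aes(.data$t, .data$reflectance,
                                       colour = factor(.data$class))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$band)) +
    ggplot2::labs(x = "timestep", colour = "class")
}
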