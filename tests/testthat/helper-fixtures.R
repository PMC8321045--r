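# Shared fixtures: small deterministic parcel sets and model configurations
# so most tests run on toy dimensions.

# a fully hand-built 2-region, 2-class standardized dataset
tiny_parcels <- function(t_steps = 6, n_bands = 2) {
  mk <- function(x) matrix(x, t_steps, n_bands)
  df <- parcel_tibble(
    parcel_id = paste0("P", 1:8),
    region = rep(c("FRH01", "FRH02"), each = 4),
    label = rep(c(0L, 0L, 1L, 1L), 2),
    series = lapply(seq(0.1, 0.8, by = 0.1), mk),
    n_classes = 2L)
  standardize_series(df, t_steps)
}

# simulated multi-class set with a region split applied
sim_split <- function(n = 400, seed = 101, n_classes = 4,
                      region_shift_scale = 0.03, noise_sd = 0.02,
                      t_steps = 15) {
  cfg <- synthetic_config(
    n_classes = n_classes, n_regions = 4, n_bands = 4,
    t_raw_range = c(12L, 20L),
    class_proportions = setNames(rep(1 / n_classes, n_classes),
                                 paste0("crop", seq_len(n_classes))),
    region_shift_scale = region_shift_scale, noise_sd = noise_sd,
    confusable_groups = list(), seed = seed)
  df <- standardize_series(simulate_parcels(n, cfg), t_steps)
  split_by_region(df, c(FRH01 = "train", FRH02 = "train",
                        FRH03 = "validation", FRH04 = "test"), quiet = TRUE)
}

toy_encoder <- function(n_bands = 4, n_classes = 4, hidden_dim = 8,
                        num_layers = 1) {
  encoder_config(n_bands = n_bands, hidden_dim = hidden_dim,
                 num_layers = num_layers, n_classes = n_classes)
}

# the reference easy-separability generator settings
easy_config <- function(seed = 11) {
  synthetic_config(region_shift_scale = 0.02, noise_sd = 0.01, seed = seed)
}
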