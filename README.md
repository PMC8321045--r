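# tripletlstm

Classification of parcel-level multispectral satellite time series — crop
type mapping from Sentinel-2-style reflectance sequences — with a
**triplet metric-learning LSTM**: a bidirectional recurrent encoder
trained jointly under inverse-median-frequency weighted cross-entropy and
a margin triplet loss, with region-aware triplet mining.

The package is for remote-sensing and agricultural-monitoring researchers
who want a fully reproducible, CPU-scale implementation of the method:
the encoder, the losses, both triplet-selection protocols, the training
loop, the evaluation suite, and a seeded crop-phenology simulator that
reproduces the statistical structure of multi-region parcel datasets so
everything is testable without downloads.

## The method

Each parcel is a T×B reflectance matrix (T = 45 timesteps, B = 13 bands
by default). A single bidirectional LSTM `f(·)` (128 hidden units per
direction) embeds it as the concatenation of the two directions' final
hidden states (E = 256); a fully connected layer and softmax
σ(z)(i) = e^{z_i}/Σ_j e^{z_j} produce class probabilities. Training
consumes triplets (anchor x_a, positive x_p, negative x_n) through three
branch roles with **shared weights**, and minimizes

    L_t = L_c(x_p, y_p) + L_c(x_a, y_a) + L_c(x_n, y_n) + λ·L_m(x_p, x_a, x_n)

where

* `L_c(x, y) = −Σ_k w_k·y(k)·log σ(f(x))(k)` is weighted cross-entropy
  with inverse-median-frequency weights `w_k = g̃ / g(k)` (g(k) the
  training frequency of class k, g̃ the median frequency), and
* `L_m = max(0, D(x_a, x_p) − D(x_a, x_n) + m)` is the triplet hinge with
  Euclidean distance `D` between embeddings and margin `m`
  (batch-averaged; defaults λ = 1, m = 1).

Triplets are mined either **region-aware** ("setup-1": anchor and
negative from the same region, positive from a different training region
— hard positives and hard negatives by construction) or **naively**
("setup-2": no region constraint). Optimization is Adam (lr 0.001) on
batches of 256 triplets with early stopping on validation accuracy.

## Worked example

```r
library(tripletlstm)

# 5,000 simulated parcels: 13 crop classes with double-logistic seasonal
# profiles over 13 bands, 4 regions with smooth regional profile shifts,
# strong class imbalance, variable raw sequence lengths
cfg <- synthetic_config(region_shift_scale = 0.02, noise_sd = 0.01, seed = 1)
parcels <- simulate_parcels(5000, cfg) |>
  standardize_series(45) |>
  split_by_region(c(FRH01 = "train", FRH02 = "train",
                    FRH03 = "validation", FRH04 = "test"))
#> split sizes: train=2501 validation=1248 test=1251

fit <- train_triplet_lstm(
  parcels,
  train_cfg = train_config(setup = "setup1", max_epochs = 10,
                           patience = 10, seed = 2))
fit
#> <triplet_lstm_fit> setup=setup1 lambda=1 margin=1 | 10 epoch(s), best validation accuracy 0.9599 at epoch 10

report <- evaluate_model(fit, dplyr::filter(parcels, split == "test"))
report
#> <metrics_report> n=1251  OA=0.5915  kappa=0.5563  f1=0.7802  precision=0.8517  recall=0.8464

embedding_separation(embed_parcels(fit$model,
                                   dplyr::filter(parcels, split == "test")))
#> # A tibble: 1 × 4
#>   within between ratio n_classes_used
#>    <dbl>   <dbl> <dbl>          <int>
#> 1   1.67    11.1  6.69             13
```

Reading the numbers: the model classifies the held-out *validation*
region almost perfectly (0.96), while the second held-out *test* region
shows the classic meadows/fodder confusion — per-class (macro) precision,
recall and f1 stay high (~0.78–0.85) but overall accuracy drops to 0.59
because the errors concentrate in the three dominant, near-identical
meadow classes under that region's particular seasonal shift. This is
exactly the regime the method targets, and `tidy(report)` /
`autoplot(report)` localize it per class. The embedding separation ratio
(between-class centroid distance over within-class spread, 6.7 here)
quantifies the discriminability the metric loss created.

`tidy(fit)` returns the per-epoch loss components and validation
accuracy, `autoplot(fit)` plots them; `tidy(report)` gives per-class
precision/recall/f1 and `autoplot(report)` the recall- or
precision-normalized confusion matrix. `embed_parcels()` exposes the
learned embeddings, and `embedding_separation()` quantifies their
class discriminability (mean between-class centroid distance over mean
within-class pairwise distance). `multirun()` repeats train/evaluate over
seeds and reports mean ± sd per metric. A thin command-line front end
with `simulate` / `train` / `embed` / `evaluate` subcommands lives in
`inst/cli/tripletlstm`.

The numbers above are from the exact code shown, run with the seeds
shown, in about three minutes on one CPU core.

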