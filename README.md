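# dailyadhere

Personalized next-day adherence prediction for gamified cognitive
training.

Mobile cognitive-training programs prescribe a play schedule (here: 5
days out of 7, 45 minutes a day, over a structured study phase), and
their effectiveness depends on participants sticking to it. This package
predicts, for each participant individually, whether **tomorrow** will
meet the *minimal adherence criterion* — at least 10 minutes (600 s) of
play — from the last `w` days of their gameplay records. It is aimed at
digital-health researchers studying engagement and dropout in
behavioral-intervention time series.

The method, per participant:

* **Adaptive window size.** De-mean the training-phase play-time series
  `x_1..x_T`, take the FFT, find the dominant non-constant bin
  `k* = argmax_k |X_k|`, and use `w = round(T / k*)`, clamped to
  `[2, 10]`, as the lookback window (fallback 3 for a flat spectrum).
* **Sliding-window framing.** Windows of the four daily predictors
  (play seconds, sessions, max level, tasks), min–max scaled on day-1–30
  statistics, advance one day at a time: `30 − w` training samples
  (targets in days `w+1..30`) and 30 test samples (targets 31–60).
* **Augmentation.** The training set can grow 6× by label-preserving
  deformations — jittering (`x + N(0, 0.01²)` per entry), scaling
  (`α ~ N(1, 0.1²)` per feature), cubic-spline time warping (knot heights
  `~ N(1, 0.2²)`), and jitter/scale stacked with warping.
* **Models.** Per-participant 1-D CNN (two Conv(64, k=2) → MaxPool(2)
  blocks → dense(32) → sigmoid), LSTM (32 units → dense(32) → sigmoid),
  and a hybrid CNN-LSTM (subsequence conv encoder → LSTM(32) → sigmoid),
  trained with Adam on binary cross-entropy. Forward/backward passes are
  compiled (RcppArmadillo) and gradient-checked in the tests.
* **Evaluation.** Precision, recall, F1, rank-based AUC (ties ½) and
  accuracy per participant, macro-averaged across the cohort; undefined
  metrics are excluded from macro means, never imputed.

Because the motivating study's raw logs are not public, the package
includes a seeded synthetic cohort generator (`simulate_cohort()`)
emulating their structure: heterogeneous per-participant adherence
propensities, preferred-weekday blocks, Normal play durations around the
45-minute target, correlated session/task/level counts, accidental
sub-threshold opens, and a multiplicative post-day-30 adherence decay.

## Worked example

```r
library(dailyadhere)

cohort <- simulate_cohort(cohort_config(n_participants = 8, seed = 42))
estimate_window_sizes(cohort)
#> # A tibble: 8 × 4
#>   participant_id window_size dominant_bin is_fallback
#>   <chr>                <int>        <int> <lgl>
#> 1 P001                     3            9 FALSE
#> 2 P002                     3            9 FALSE
#> 3 P003                     2           13 FALSE
#> # i 5 more rows

result <- run_experiment(experiment_config(
  cohort = cohort, families = "cnn",
  techniques = c("none", "jitter_time_warp"),
  training = training_config(epochs = 100), seed = 42
))
glance(result)
#> # A tibble: 2 × 10
#>   family technique        n_participants precision recall    f1   auc accuracy
#>   <chr>  <chr>                     <int>     <dbl>  <dbl> <dbl> <dbl>    <dbl>
#> 1 cnn    jitter_time_warp              8     0.401  0.377 0.429 0.556    0.596
#> 2 cnn    none                          8     0.477  0.394 0.484 0.579    0.667
```

Each row is one cell of the comparison grid: macro averages over the 8
personalized CNNs evaluated on their own 30 test days. This default
cohort is deliberately hard — propensities are heterogeneous and
adherence decays after day 30, so day-by-day prediction sits well below
perfect (macro accuracy 0.67 without augmentation here). On a cohort with
strong, stable periodic structure the same pipeline recovers the schedule
almost completely:

```r
structured <- cohort_config(n_participants = 8,
                            adherence_base_rate_params = c(600, 10),
                            weekly_period = 5, preferred_days_per_week = 3,
                            play_noise_sd_minutes = 2, decay_rate = 1,
                            off_day_multiplier = 0.02,
                            accidental_open_prob = 0, seed = 42)
glance(run_experiment(experiment_config(cohort = structured,
                                        families = "cnn",
                                        techniques = "none", seed = 42)))
#> # A tibble: 1 × 10
#>   family technique n_participants precision recall    f1   auc accuracy
#>   <chr>  <chr>              <int>     <dbl>  <dbl> <dbl> <dbl>    <dbl>
#> 1 cnn    none                   8     0.843  0.973 0.898 0.937    0.862
```

Single-participant pieces are available directly:

```r
log1 <- dplyr::filter(cohort, participant_id == "P001")
split <- make_supervised(log1, window_size = 3)
model <- fit_adherence_model(split$train, architecture_spec("cnn", 3))
model
#> <adherence_model> cnn, window 3 x 4 features, trained on 27 samples
#>   (100 epochs, final loss 0.3058)
round(predict(model, split$test[1:5, ]), 3)
#> [1] 0.585 0.142 0.074 0.023 0.012
```

Those five numbers are the model's probabilities that participant P001
meets the 10-minute criterion on days 31–35; with the default 0.5
threshold only day 31 would be called adherent.

`autoplot()` methods draw the cohort adherence raster, training-loss
curves and the technique-comparison grid; `tidy()`/`glance()` return the
per-participant table and the macro grid.

## Command line

A thin CLI wraps the same functions:

```sh
exec/dailyadhere simulate --config experiment.yaml --out cohort.csv
exec/dailyadhere estimate-windows --cohort cohort.csv
exec/dailyadhere run --config experiment.yaml --seed 1 --out runs/exp1
exec/dailyadhere report --runs runs/exp1
```

The YAML config mirrors `experiment_config()` (blocks `cohort:`,
`label:`, `window:`, `augmentation:`, `model:`, `training:`, `output:`);
every field has a default.

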