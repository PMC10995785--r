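# borcast — hospital bed occupancy forecasting

`borcast` is an R implementation of a hospital **bed occupancy rate** (BOR)
forecasting pipeline for ward- and room-level planning. Hourly bed-level
status records are aggregated into daily occupancy rates

> BOR = occupied beds / capacity ∈ [0, 1],

windowed into 3/7/30-day sequences, and forecast one day ahead by two
recurrent architectures:

* a **base model** — stacked (bi)LSTM layers with LeakyReLU activations, an
  *attention-with-context* pooling layer
  (`u_t = tanh(W h_t + b)`, `α = softmax_t(u_t · u_c)`, `c = Σ α_t h_t`)
  and a dense + sigmoid head bounding predictions to (0, 1);
* a **static+dynamic fusion model** — the same dynamic stack concatenated
  with a two-layer dense/dropout branch over the 14 static room attributes
  (room grade code plus 13 capability flags).

Models are compared over the study grid of twelve configurations
({LSTM, Bi-LSTM} × {W7D, W30D, R3D, R7D, RS3D, RS7D}) with expanding 5-fold
time-series cross-validation and MAE / MSE / RMSE / R² reporting. Because
real bed-management extracts are institution-private, the package includes a
synthetic hospital simulator (hierarchical ward/room/bed layout, weekly,
seasonal and holiday structure, static-attribute effects, AR(1)
autocorrelated latent demand) that emulates the record schema end to end.
The recurrent networks, attention layer and training loop (Adam, MSE loss,
early stopping on validation MAE) are implemented natively in the package
with hand-derived backpropagation, verified against numerical gradients in
the test suite.

## Worked example

```r
library(borcast)

# a small synthetic hospital with a weekly occupancy pattern
layout   <- build_layout(n_wards = 5, rooms_per_ward = 8, capacity_dist = 6, seed = 9)
profiles <- sample_static_profiles(layout, rep(0.2, 13), seed = 9)
config   <- sim_config("2022-01-01", "2022-12-31", mu = 0.4,
                       beta_dow = c(.6, .3, .1, -.1, -.4, -.9, -1.1),
                       rho = 0.5, sigma = 0.15, seed = 31)
daily    <- simulate_daily_states(layout, profiles, config)

# daily ward table -> encoded dataset -> 7-day windows
tab <- occupancy_table(daily, "ward")
ds  <- encode_and_normalize(tab, "ward", train_range = c("2022-01-01", "2022-10-31"))
ws  <- make_windows(ds, window_len = 7)

# expanding 5-fold time-series cross-validation of the Bi-LSTM model
spec <- model_spec("bilstm", window_len = 7, units = 16, learning_rate = 3e-3, seed = 14)
res  <- run_tscv(spec, ws, n_folds = 5,
                 config = train_config(max_epochs = 30, batch_size = 128, patience = 6))
fold_summary(res$reports)
compute_metrics(ws$y, persistence_baseline(ws))$mae
```

```
       model   fold   mae   mse  rmse    r2
      <char> <char> <num> <num> <num> <num>
1: bilstm_w7      1 0.059 0.006 0.076 0.758
2: bilstm_w7      2 0.059 0.005 0.074 0.777
3: bilstm_w7      3 0.056 0.005 0.069 0.800
4: bilstm_w7      4 0.057 0.005 0.072 0.784
5: bilstm_w7      5 0.056 0.005 0.071 0.763
6: bilstm_w7   Mean 0.057 0.005 0.073 0.776

persistence MAE over all samples: 0.143
```

Each fold row is the model retrained on all earlier blocks and evaluated on
the next one; the `Mean` row is the arithmetic fold mean rounded half-up to
3 decimals. An MAE of 0.057 means the forecast misses tomorrow's ward
occupancy by about 5.7 percentage points of capacity, explaining ~78% of the
day-to-day variance (R²) where the naive carry-forward baseline misses by
14.3 points — the weekly admission/discharge rhythm is what the recurrent
model captures and the baseline cannot.

A full analysis workflow (simulate → preprocess → tune + 12-model grid →
report/plots/dashboard feed) lives in `analysis/01_simulate.R` …
`analysis/04_report.R`, writing its tables under `results/`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/simulate.R`, `R/scenarios.R` | synthetic hospital generator and pinned study scenarios |
| `R/preprocess.R` | status imputation, daily aggregation, date features, encoding/scaling |
| `R/windows.R` | sliding windows, chronological splits, expanding CV folds |
| `R/nn.R`, `R/forecaster.R` | native (bi)LSTM + attention engine, training loop, baselines |
| `R/experiments.R` | hyperparameter search, per-model CV, the 12-model grid |
| `R/evaluate.R` | metrics, fold summaries, plots, dashboard feed |
| `analysis/` | numbered workflow scripts |
| `vignettes/methods.Rmd` | model, simulator and design-choice documentation |
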