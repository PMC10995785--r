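Package: borcast
Title: Hospital Bed Occupancy Forecasting with Recurrent Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for forecasting hospital ward- and room-level
    bed occupancy rates one day ahead from hourly bed-status records. Includes a
    synthetic hospital simulator (hierarchical ward/room/bed layout, weekly and
    seasonal occupancy structure, holiday effects, static room attributes,
    autocorrelated latent demand), preprocessing of bed-level records into daily
    occupancy tables and model datasets, leakage-free sliding-window sample
    construction with chronological splits and expanding 5-fold time-series
    cross-validation, LSTM and bidirectional LSTM forecasters with an
    attention-with-context pooling layer and an optional static-feature fusion
    branch (implemented natively with manual backpropagation and Adam), plus
    evaluation (MAE, MSE, RMSE, R squared), fold-summary reporting, plots, and a
    dashboard data export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
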