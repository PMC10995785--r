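---
title: "Forecasting hospital bed occupancy: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting hospital bed occupancy: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(borcast)
```

## The problem

Hospitals track every bed's status (patient present, ready for admission,
awaiting cleaning after discharge) at hourly resolution. Aggregated per day,
these records yield the *bed occupancy rate* (BOR) of each ward and each room
— occupied beds divided by capacity, a number in $[0,1]$. Forecasting
tomorrow's BOR from the recent history supports admission planning, staffing
and transfer decisions. `borcast` implements that forecasting pipeline end to
end: a synthetic hospital simulator, preprocessing of bed-level records into
daily occupancy tables, leakage-free sliding-window sample construction,
recurrent forecasters with attention and optional static-feature fusion, and
evaluation with expanding time-series cross-validation.

Because real bed-management extracts are institution-private, the package
ships a generator that emulates their statistical structure; every empirical
claim made by the test suite is therefore a claim about that synthetic
regime, discussed at the end.

## From records to model datasets

A raw record is `(timestamp, ward, room, bed, status)`, where the status
field carries `"admittable"` or `"discharge"` for empty beds and is *missing*
when a patient occupies the bed. `impute_bed_status()` therefore maps missing
to 1 and both recorded states to 0; any other value is a data error.

`aggregate_daily()` reduces each bed's 24 hourly indicators to a daily
occupancy. The reduction rule is a genuinely open choice — a day-level
snapshot at a reference hour and a daily mean are both defensible — so both
are implemented (`daily_rule`), with the mean, rounded half-up, as the
default: it is robust to brief status flips around admission and discharge.
Occupied counts are summed to the room or ward, and ward rows equal the
capacity-weighted aggregate of their rooms by construction (tested as an
invariant).

Date features are the calendar year, month, ISO week-of-year (1–53),
day-of-month, ISO weekday and a 0/1 public-holiday flag. The ISO convention
is used for week and weekday; nothing downstream depends on the convention,
only on its stability. Holidays are supplied as an arbitrary date set; a
27-day Korean public-holiday calendar for mid-2020 through late-2022 ships
as a plain-text fixture (`korean_holidays()`). Weekends are deliberately not
folded into the holiday flag since the weekday feature already encodes them.

`encode_and_normalize()` builds the four dataset variants (ward, room,
room+static). Categorical columns are *ordinal*-encoded against a sorted
vocabulary fixed on the training rows — unseen categories map to a reserved
code 0 and are logged. Scaling is min–max, fitted on the chronological
training range only and applied everywhere without clipping, so a test-range
value outside the training envelope scales outside $[0,1]$; that is
intentional (an affine map, not a censor). The target rate is never rescaled:
it is already in $[0,1]$, which keeps the sigmoid output head directly
interpretable. These choices favour simplicity and bounded inputs for a
small recurrent network over one-hot expansion, at the cost of imposing an
artificial order on categories; with pooled models and an entity-identifier
feature this is the standard compromise.

## Windows, splits and folds

`make_windows()` slides a length-$L$ window (stride 1) over each entity's
contiguous daily series; the target is the occupancy rate $h$ days after the
window ($h = 1$ by default, exposed as a parameter). An entity with fewer
than $L + h$ days contributes nothing. Windows never span entities.

Partition membership is decided by the **target date only**: a validation
sample's window may legitimately read features from the training period,
because at deployment time the past is observable. What must never happen —
and what the test suite checks over randomized configurations — is a
training *target* on or after a validation/test target.

`tscv_folds()` implements expanding-window cross-validation: the span of
target dates is cut into $k+1$ equal contiguous blocks; fold $i$ trains on
blocks $1..i$ and validates on block $i+1$. An expanding (rather than
sliding) scheme was chosen because it is the common default and maximizes
training data per fold; either reading is consistent with "shifting periods".
Folds are built over the train+validation span only, never the held-out test
range.

## The forecasters

Both architectures are implemented natively in the package as vectorised
batch matrix operations with hand-derived backpropagation through time; the
test suite verifies every gradient against central-difference numerical
differentiation ($10^{-4}$ relative tolerance) and the parameter counts
against closed forms.

**Base model.** For a window $X \in \mathbb{R}^{L \times F}$:

$$ H^{(1)} = \mathrm{LSTM}(X), \quad A^{(1)} = \mathrm{LeakyReLU}(H^{(1)}) $$
$$ H^{(2)} = \mathrm{LSTM}(A^{(1)}), \quad A^{(2)} = \mathrm{LeakyReLU}(H^{(2)}) $$
$$ c = \mathrm{AttnCtx}(A^{(2)}), \quad \hat y = \sigma(w^\top \mathrm{LeakyReLU}(c) + b) $$

The bidirectional variant runs each LSTM layer in both directions and
concatenates, doubling the hidden dimension. The sigmoid head bounds every
prediction strictly inside $(0,1)$, matching the rate target.

**Attention with context.** The pooling layer is the additive
context-vector form:
$u_t = \tanh(W h_t + b)$, $\alpha_t = \mathrm{softmax}_t(u_t^\top u_c)$,
$c = \sum_t \alpha_t h_t$, with $W$, $b$ and $u_c$ learned. The layer is
named in the literature but rarely written out; this is the widely used
formulation, and its stated invariants (positive weights summing to one,
context in the convex hull of the hidden states) are tested.

**Fusion model.** For room-level forecasts the 14 static room variables
(grade code plus 13 capability flags) pass through two dense + LeakyReLU +
dropout blocks; the result is concatenated with the dynamic branch's pooled
context and fed to the final dense + sigmoid head. Dropout (default 0.3) is
applied only in the static branch, mirroring its role as an overfitting
guard on the low-dimensional static pathway.

**Defaults that the architecture description leaves open** (all exposed as
parameters): LeakyReLU negative slope 0.01; static-branch widths (64, 32);
early stopping on validation MAE with patience 10 within a 200-epoch budget;
batch size 256; Adam at the spec's learning rate with MSE loss. One pooled
model is trained per configuration across all entities, with the encoded
entity identifier as an input feature — the dataset schema lists the
ward/room abbreviation among the variables, which implies pooling rather
than per-entity models. Training is fully deterministic given the spec seed
(seeded initialisation, shuffling and dropout); early stopping restores the
best-validation weights, and a non-finite loss aborts with the offending
epoch named.

## Experiments

The study grid is the cross of two architectures with six configurations —
W7D, W30D (ward level, windows 7/30), R3D, R7D (room level, windows 3/7) and
RS3D, RS7D (room level with static fusion) — twelve models.
`search_hyperparameters()` evaluates a units × learning-rate grid (default
$\{16,32,64,128\} \times \{10^{-2},10^{-3},10^{-4}\}$, a declared stand-in
for an unreported tuner space) under a budget, breaking ties toward smaller
units then smaller learning rate. Tuning runs once on fold 1 and the winner
is reused across folds; per-fold re-tuning would multiply cost without a
stated mandate.

Evaluation uses MAE, MSE, RMSE $= \sqrt{\mathrm{MSE}}$ and
$R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$ (per evaluation set, not averaged over
entities; it may be negative, and is undefined for constant targets).
Report cells are rounded half away from zero at 3 decimals, percentages at 1
decimal, matching the precision convention of published occupancy tables.
`fold_summary()` appends the arithmetic-mean row per model.

## The simulator

The generator mirrors the hierarchy of a real bed-management extract: wards
contain rooms, rooms have integer capacities, and each room carries the 14
static attributes. Occupancy follows a latent-logit process: for room $r$ on
day $t$,

$$ z_{rt} = \mu + a_r\,\beta_{\mathrm{dow}(t)}
  + \beta_s \sin\!\big(2\pi\,\mathrm{doy}(t)/365.25\big)
  + \beta_h \mathbf{1}\{t \in \mathrm{holidays}\}
  + \gamma^\top s_r + e_{rt}, $$

$e_{rt} = \rho e_{r,t-1} + \varepsilon_{rt}$,
$\varepsilon_{rt} \sim N(0, \sigma^2)$ (initialised from the stationary
distribution to avoid a burn-in transient), and the occupied count is
$\mathrm{Binomial}(\mathrm{capacity}_r, \mathrm{logistic}(z_{rt}))$. The
multiplier $a_r = 1 + m \cdot s_{r1}$ optionally lets the first static flag
scale the weekly amplitude ($m = 0$ by default), giving the static table
predictive content beyond a level shift — the regime in which static fusion
can help. A room-level binomial with AR(1) latent noise is the smallest
mechanism that reproduces what the pipeline assumes (rates, weekly/seasonal/
holiday structure, temporal autocorrelation, static-attribute modulation);
lengths of stay, admission flows and surge dynamics are deliberately out of
scope. Status is constant within a day — the hourly emission exists to
exercise the aggregation path, and `aggregate(expand(S)) = S` holds exactly
and is tested.

What passing tests on this generator do **not** show: real occupancy series
have length-of-stay autocorrelation, census effects around weekends and
holidays that interact, structural breaks (unit closures, outbreaks), and
heavy-tailed room-level behaviour that a binomial cannot produce. Results on
the synthetic regime demonstrate that the pipeline is correct and that the
models can learn the structure they are designed for — not that they attain
any particular accuracy on hospital data.

## Pinned study scenarios and problem sizes

Two fixed scenarios define the conditions under which the model-comparison
properties are evaluated; they are package functions so that tests, the
acceptance script and the analysis scripts share them verbatim.

* `scenario_weekly_wards()` — 20 wards of 400 beds over 400 days with a
  strong deterministic day-of-week pattern and no latent noise; the binomial
  sampling noise is then roughly 0.025 on the rate scale at half occupancy.
  On this regime the bidirectional 7-day model must beat both the
  persistence and the global-mean baseline (majority of 3 pinned seeds); it
  typically reaches a test MAE near the noise floor (~0.02) against ~0.14
  for the baselines.
* `scenario_static_amplitude()` — 40 rooms of 15 beds over 400 days where
  the first static flag damps the weekly amplitude by 90% and shifts the
  baseline, with moderate AR(1) noise. Here the static table genuinely
  informs the forecast, and the fusion model's median test MAE over 3 seeds
  must not trail the dynamic-only model's.

Model sizes in these scenarios (units 16, ≤ 50 epochs, batch 256) and the
analysis scripts' hospital (6 wards, 30 rooms, ~910 days) were chosen so the
full grid and the property suites complete in minutes on a single CPU while
leaving the learnable structure intact; they are the package's declared
study conditions, not tuned quantities.

## Numerical and degenerate-input behaviour

Softmax scores in the attention layer are max-shifted before
exponentiation. Min–max scaling of a constant column yields all zeros (with
a message) rather than 0/0. $R^2$ on constant targets is returned as `NA`
with a warning. Rounding for report cells is half away from zero, not
banker's rounding. Hyperparameter-search ties are broken deterministically
(smaller units, then smaller learning rate). Entities too short for a window
contribute zero samples and a log line rather than an error; an entity with
non-contiguous dates is an error, since silent gap-spanning windows would
corrupt the supervised pairs.

## Known limitations

* The simulator's binomial room process cannot produce over-dispersed or
  regime-switching occupancy; effect sizes are on the logit scale and only
  roughly map to rate-scale intuition.
* Ordinal encoding imposes an arbitrary order on entity identifiers; with
  many entities a learned embedding would be preferable but is outside the
  reproduced design.
* Forecasts are point estimates one day ahead; multi-step and probabilistic
  forecasting are non-goals.
* The native network engine favours transparency and testability over raw
  speed; it is adequate for the study's problem sizes but not for
  thousands of entities at hundreds of units.
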