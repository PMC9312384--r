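# ppactiv

Psychophysiological (PP) activation analysis for wearable recordings of
professional traders — or anyone whose wristband streams blood volume pulse,
electrodermal activity, skin temperature, heart rate, inter-beat intervals
and acceleration while timestamped events (market moves, transactions)
happen around them.

The core quantity is the **squared Mahalanobis distance of a physiological
feature vector from its own expanding baseline**. Eleven features are
extracted at 1 Hz with trailing windows — four time-domain HRV statistics
(mHR, mRRi, SDNN, RMSSD), three electrodermal features (mean amplitude,
rate-normalized slope, skin-conductance-response count), three
blood-volume-pulse summaries (mean absolute value, min, max) and the
skin-temperature slope — and scored as

    d_M(y_t) = (y_t − μ_t)ᵀ Σ_t⁻¹ (y_t − μ_t),

where μ_t and Σ_t are the sample mean and covariance of y_1 … y_t, so the
score at time t never looks ahead. On top of d_M the package computes:

* per-day activation metrics: average activation, mild (> μ + 1.5 σ) and
  extreme (> μ + 3 σ) activation proportions, and mean episode length, plus
  cohort histograms;
* **Granger causality** tests of market-index fluctuations against
  minute-averaged activation (first differences, SSR χ² statistic, lag 10),
  with Holm-Bonferroni correction per index and Kolmogorov–Smirnov p-value
  uniformity diagnostics;
* an **attribution regression** of average daily activation on business
  division, gender, trading experience, transaction amount/count and market
  volatility;
* a transaction-centered **event study** of z-scored activation in twelve
  5-minute windows from −30 to +30 minutes, with a 95% confidence band;
* a fully seeded **synthetic cohort generator** (signals, markets,
  transactions, covariates) with planted ground truth, so every stage can be
  validated against a recoverable truth.

## Worked example

Simulate a small cohort, score one trader-day, and label episodes:

```r
library(ppactiv)

spec <- cohort_spec(n_traders = 4, days_per_trader = 1, seed = 3)
rec  <- generate_physiology(spec, trader = 1, day = 1)
rec
#> <physio_recording> trader T01, 2020-03-02: channels [BVP, EDA, TEMP, HR,
#>   ACC_X, ACC_Y, ACC_Z], 27544 beats, span 23400 s

fs  <- assemble_feature_series(rec)
act <- activation_series(fs)
act
#> <activation_series> trader T01, 2020-03-02 (overall): 22802 valid rows,
#>   day mean 10.05, sd 6.66

summarize_day(act)
#>   trader_id        day average_activation mild_proportion extreme_proportion
#> 1       T01 2020-03-02           10.04644        7.679151           1.622665
#>   activation_length_s n_valid
#> 1            24.31944   22802
```

The day's mean activation (~10) sits near the χ²₁₁ mean of 11, as it should
for a baseline day scored against adaptive moments; 7.7% of the day is
mildly activated and the average mild episode lasts about 24 s. Running the
whole pipeline on a cohort —

```r
cfg <- pipeline_config(out_dir = "results",
                       spec = cohort_spec(seed = 42, dropout_rate = 0.12))
res <- run_pipeline(cfg)
res$event_study
```

— writes `summaries.csv`, `histograms.json`, `granger_scan.json`,
`attribution.json` and `event_study.json`. On the default synthetic cohort
the event-study profile peaks in the +15..+25-minute windows after a
transaction with a smaller local peak just before it (these bumps are
planted by the generator), the Kolmogorov–Smirnov diagnostic flags the one
market index that is planted to lead activation, and the experience
coefficient of the attribution regression comes out negative.

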