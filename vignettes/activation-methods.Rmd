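---
title: "Measuring psychophysiological activation from wearable recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring psychophysiological activation from wearable recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppactiv` quantifies the *psychophysiological (PP) activation* of a person
wearing a multichannel wristband — the collective deviation of their
physiological signals from their own baseline — and relates it to events in
their environment: market-index fluctuations, the financial transactions they
execute, and stable personal covariates. This vignette explains the model and
the analysis choices; the README shows a worked example.

## The activation metric

Eleven features are extracted at 1 Hz from four signal families, each over a
trailing window so that the value at time $t$ never uses data after $t$:

* **Heart-rate variability** (from the inter-beat-interval stream, 5-minute
  window): `mHR` the mean heart rate in beats/min, computed as 60 over the
  mean RR interval; `mRRi` the mean RR interval (ms); `SDNN` the sample
  standard deviation of the RR intervals (ms); `RMSSD` the root-mean-square
  of successive RR differences (ms), over beat pairs that fall inside the
  window. `mHR` is derived from the same inter-beat stream as the other
  three — not from the device's own HR channel — so all four HRV features
  share a single source of truth; the HR channel is retained for quality
  control only.
* **Electrodermal activity** (4 Hz, 5-minute window): `mAmp` the mean skin
  conductance (uS); `Slope` the mean absolute first difference, reported per
  second so it is invariant to the sampling rate; `Events` the number of
  skin-conductance responses, where a response is a strictly-rising run of
  the signal containing a sub-segment that rises more than 0.05 uS in less
  than 5 s. One rising run counts as one event no matter how long it is —
  without that merge rule a single slow rise would be counted dozens of
  times.
* **Blood volume pulse** (64 Hz, 5-minute window): mean absolute value,
  minimum and maximum of the photoplethysmographic signal.
* **Skin temperature** (4 Hz): the least-squares slope over a trailing
  60-second window, as the operationalization of the instantaneous rate of
  change. The feature windows for EDA and BVP are not separately
  standardized anywhere, so they default to the same 300 s as the HRV
  window; all windows are configurable.

A row of the feature matrix is valid only when the full window has elapsed
since the session start and every feature is computable; nothing is imputed.

Stacking the features into $y_t \in \mathbb{R}^{11}$, activation is the
squared Mahalanobis distance

$$ d_M(y_t) = (y_t - \mu_t)^\top \Sigma_t^{-1} (y_t - \mu_t), $$

where $\mu_t$ and $\Sigma_t$ are the sample mean and covariance of
$y_1,\dots,y_t$ — an *expanding* window from the start of the trading day
through $t$, so the score is causal and carries no look-ahead bias. The
quadratic form is used as printed, without a square root. Implementation
details that matter:

* The streaming update maintains Welford-style centered sums (one pass,
  numerically stable) and must agree with a from-scratch batch recomputation
  to $10^{-8}$ at every $t$; the test suite enforces this.
* $\Sigma_t$ is regularized as $\Sigma_t + \varepsilon\,
  \overline{\mathrm{diag}(\Sigma_t)}\, I$ with $\varepsilon = 10^{-6}$,
  because the integer-valued `Events` column is typically constant early in
  the day and makes the raw covariance singular.
* Rows are invalid until `max(300, 5 d)` valid rows have accumulated
  (burn-in), a covariance-conditioning requirement.
* With oracle moments and Gaussian features, $d_M \sim \chi^2_{11}$; the
  acceptance suite checks the mean and the 95% tail at $n = 20{,}000$.

A trader-day is summarized by four metrics: the **average activation** (mean
$d_M$ over valid samples), the **mild** and **extreme activation
proportions** (percentage of valid samples with $d_M > \mu + 1.5\sigma$ and
$d_M > \mu + 3\sigma$, where $\mu, \sigma$ are the day's mean and standard
deviation of $d_M$; mild includes extreme), and the **activation length**
(mean duration of maximal contiguous mild runs, with no gap merging). The
thresholds 1.5 and 3 are fixed constants of the method, not fitted. Because
$\mu$ and $\sigma$ are computed over the whole day including the labeled
periods, thresholding is in-sample; that is the definition adopted here, and
a degenerate day with $\sigma = 0$ simply has no episodes.

## Granger causality against market indices

The 1 Hz activation series is averaged within calendar minutes
(`floor(epoch/60)`; partial leading/trailing minutes dropped), intersected
with the minute grid of each market index, and both series are first
differenced to remove nonstationarity. For each trader-day and index the
null "index fluctuations do not Granger-cause activation" is tested by
comparing restricted (own lags only) and unrestricted (plus 10 lags of the
index differences) OLS fits through the sum-of-squared-residuals statistic

$$ n_\mathrm{eff} \frac{SSR_r - SSR_u}{SSR_u} \sim \chi^2_{p},
   \qquad p = 10, $$

with $n_\mathrm{eff}$ the rows remaining after lag embedding. The statistic
is verified in the tests against an independent reference implementation of
the same SSR form on frozen data. The lag of 10 minutes is a fixed order,
not a searched maximum. Multiplicity is controlled per index family —
all trader-days of one index — with Holm-Bonferroni at 5%
(`stats::p.adjust`), and a one-sample Kolmogorov-Smirnov statistic on the
raw p-values of each family diagnoses departure from the uniform
distribution expected under the global null. Two caveats the tests make
visible: the $\chi^2$ reference is asymptotic and slightly liberal at
$n \approx 390$ (the type-I error simulation band is 3-8%, not a point
value), and with hundreds of tests per family the KS diagnostic is sensitive
enough to notice that liberality.

## Attribution regression

Average daily activation is regressed on the trader's business division
(one-hot, first level alphabetically as reference), gender, mean transaction
amount of the day (in $ millions), years of trading experience, number of
transactions, and the per-index market volatility of the day (standard
deviation of minute-level first differences):

$$ y_{i,t} = \alpha + \beta\,\mathrm{bis}_i + \gamma\,\mathrm{gen}_i
   + \delta\,\mathrm{amt}_{i,t} + \theta\,\mathrm{exp}_i
   + \zeta\,\mathrm{numT}_{i,t} + \eta^\top \mathrm{vol}_t. $$

Ordinary least squares with classical standard errors is the default —
cluster-robust (by trader) errors are available by flag since trader-days
repeat within trader, and amounts can be `log1p`-transformed by flag.
Zero-trade days are kept with `amt = 0` to preserve the panel. Gender enters
as a coded binary variable, so its coefficient is exactly the male-female
difference.

## Event study around transactions

Activation is z-scored within trader-day ($z_t = (d_M(y_t) - \mu)/\sigma$) so
levels are comparable across traders, then averaged in twelve half-open
5-minute windows $[-30,-25), \dots, [+25,+30)$ minutes around each
transaction — half-open so the windows partition the hour. Profiles are
averaged first across a trader-day's transactions, then across trader-days
(unweighted two-level mean), with a 95% band of $\pm 1.96\,s/\sqrt{n}$
across trader-day profiles; a seeded bootstrap band over trader-days is
available. Transactions closer than 30 minutes to the session edges are
skipped and counted; transactions less than an hour apart both contribute.

## The synthetic cohort and what it does (not) show

No recordings of the original study are available, so the package ships a
fully seeded generator that emulates the study conditions: 55 traders, five
6.5-hour sessions each, six signal channels at the public device rates
(BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz, HR 1 Hz, three-axis ACC 32 Hz), eight
market indices on a 1-minute grid, about eight log-normal transactions per
trader-day (median $1M), and an optional 12% trader-day dropout that
reproduces the 242-trader-day panel. Signal models are deliberately simple —
an AR(1) heart period (mean 0.85 s, sd 0.05 s, $\phi=0.95$ at beat scale),
Poisson skin-conductance responses (2/min baseline, amplitude 0.1-0.5 uS,
exponential decay $\tau = 40$ s), a pulse-rate oscillation with
multiplicative amplitude noise for BVP, random-walk temperature and markets.
The generator validates the *analysis*, not physiological realism: real
recordings have circadian structure, posture and motion artifacts,
device-contact noise and non-Gaussian tails that these models do not
emulate, so green tests certify the statistical machinery, not field
performance.

Planted structure and the design choices behind it:

* **Episodes.** During a planted arousal episode (30 s onset/offset ramps)
  the heart period mean drops 10% and its variability 30%, the SCR rate
  quadruples, BVP amplitude rises 1.5x and skin temperature gains
  +0.003 degC/s, each scaled by the episode magnitude. A single planted
  episode on a baseline day is recovered by the mild-episode labeling with
  Jaccard overlap >= 0.5 in the large majority of seeded runs.
* **Post-transaction bumps.** Each transaction plants an activation episode
  at +15..+25 minutes (and a smaller one at -5..0), the shape the event
  study must recover — and does, both from directly constructed z-series and
  through the full physiological chain.
* **Market coupling.** One non-negative AR(1) driver per coupled index per
  day ($\phi = 0.9$ at minute scale, rectified) is injected into the index's
  increments *lag* minutes early, so the market leads activation; coupled
  traders receive the same driver, centered to zero day-mean, as
  physiological forcing. Centering matters: a forcing with a positive
  day-mean both shifts the day's mean activation for coupled traders and
  interacts with the planted attribution drift, while the minute-scale
  fluctuations are all the Granger test needs. One driver per index (rather
  than one per trader) keeps the index variance bounded when many traders
  couple to the same index. The rectification exists because the Mahalanobis
  metric responds to the magnitude of deviations: a sign-symmetric forcing
  would leave activation uncorrelated with the signed market increments.
* **Attribution effects.** A day's planted mean-activation uplift is
  delivered by a linear drift in the forcing over the day. This choice is
  forced by a genuine property of the metric: the expanding-moment
  normalization *absorbs* transient episodes (measured on this generator,
  the day-mean of $d_M$ is nearly flat in both episode count and episode
  magnitude once the covariance has adapted), but it permanently lags a
  trend, so a drift raises mean activation monotonically in the slope. The
  slope-to-uplift response curve was measured once from the generator itself
  (12 trader-days per anchor, transaction bumps present) and is stored in
  the spec; planting inverts it by interpolation. The planted experience
  effect defaults to -0.02 per year — more experienced traders are calmer —
  with small division, gender, amount and count effects.

Known limitations, stated rather than hidden: end-to-end Granger power
through the physiological chain is moderate (the 5-minute feature windows
and the adaptive covariance smear minute-scale signals), so Holm-corrected
detection counts in a default cohort sit well below the per-pair rejection
rate; coupled traders show an attenuated (~2x) attribution response and
extra day-level noise, so end-to-end coefficient recovery is approximate —
the regression machinery itself is verified separately against directly
planted panels where recovery is exact (noiseless) or calibrated (2-SE
coverage >= 93%).

## Numerical and scale choices

Problem sizes used by the test-suite simulations were chosen to make the
checks sharp but quick: type-I error over 500 replicates of 390-minute days,
power over 200, KS calibration over 200 replicates of 5,000 p-values,
attribution coverage over 200 replicates of 250 trader-days, event-study
recovery over 40 trader-days, and the determinism check over two complete
runs of the full 275-trader-day default cohort. Timestamps are epoch seconds
UTC throughout; minute bucketing is `floor(epoch/60)`; sub-seeds for every
trader-day, day and stream are mixed deterministically from the master seed,
so any subset of a cohort regenerates bit-identically.
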