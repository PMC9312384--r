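t0 <- 1585000000

test_that("HRV features match closed forms on constructed RR streams", {
  # constant RR = 1 s: zero-variance window
  ibi <- make_ibi(rep(1, 400), t0)
  f <- hrv_features(ibi, t0 + 350, window_s = 300)
  expect_equal(unname(f), c(60, 1000, 0, 0))

  # alternating 0.8 / 1.0 s: closed-form mean, SDNN, RMSSD
  rr <- rep(c(0.8, 1.0), 150)
  ibi <- make_ibi(rr, t0)
  t_eval <- t0 + sum(rr)  # window (t-300, t] holds the trailing beats
  f <- hrv_features(ibi, t_eval, window_s = 300)
  in_win <- cumsum(rr) > sum(rr) - 300
  rr_w <- rr[in_win]
  expect_equal(unname(f["mRRi"]), mean(rr_w) * 1000)
  expect_equal(unname(f["mHR"]), 60 / mean(rr_w))
  expect_equal(unname(f["SDNN"]), sd(rr_w) * 1000)
  expect_equal(unname(f["RMSSD"]), 200)  # successive diffs all +/-0.2 s
  expect_equal(unname(f["mHR"]), 60 / 0.9, tolerance = 1e-3)

  # beat-count preconditions: < 2 beats -> all NA; 2 beats -> only RMSSD NA
  expect_true(all(is.na(hrv_features(ibi, t0 + 0.5))))
  two <- make_ibi(c(1, 1), t0)
  f2 <- hrv_features(two, t0 + 2, window_s = 300)
  expect_false(anyNA(f2[c("mHR", "mRRi", "SDNN")]))
  expect_true(is.na(f2["RMSSD"]))
})

test_that("SDNN/RMSSD are invariant to time-shifting the beat stream", {
  set.seed(4)
  rr <- runif(300, 0.7, 1.0)
  a <- hrv_features(make_ibi(rr, t0), t0 + 250)
  b <- hrv_features(make_ibi(rr, t0 + 7777), t0 + 7777 + 250)
  expect_equal(a, b)
})

test_that("SCR detector applies the rise-amount / rise-time rule", {
  flat <- make_channel("EDA", 4, 120, function(ts) 0.5 + 0 * ts, t0)
  expect_equal(nrow(detect_scr_events(flat)), 0)

  # slow ramp: 0.02 uS/s for 10 s -> any 5 s sub-segment rises 0.1 > 0.05,
  # and the whole rising run merges into ONE event
  ramp1 <- make_channel("EDA", 4, 120, function(ts)
    0.5 + 0.02 * pmin(pmax(ts - 20, 0), 10), t0)
  ev <- detect_scr_events(ramp1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_uS, 0.2, tolerance = 1e-6)

  # two fast rises (0.06 uS in 3 s) separated by a 60 s plateau -> 2 events
  rise2 <- function(ts) {
    0.5 + 0.02 * pmin(pmax(ts - 10, 0), 3) + 0.02 * pmin(pmax(ts - 73, 0), 3)
  }
  ev2 <- detect_scr_events(make_channel("EDA", 4, 150, rise2, t0))
  expect_equal(nrow(ev2), 2)

  # sub-threshold rise (0.04 uS in 3 s) -> nothing
  small <- make_channel("EDA", 4, 60, function(ts)
    0.5 + 0.0133 * pmin(pmax(ts - 10, 0), 3), t0)
  expect_equal(nrow(detect_scr_events(small)), 0)

  # events fire only on rises: the time-reversed ramp has none
  rev1 <- make_channel("EDA", 4, 120, function(ts)
    0.7 - 0.02 * pmin(pmax(ts - 20, 0), 10), t0)
  expect_equal(nrow(detect_scr_events(rev1)), 0)

  expect_error(detect_scr_events(flat, span = c(t0 - 50, t0 + 10)),
               class = "ppactiv_range")
})

test_that("EDA features match closed forms and scaling laws", {
  const <- make_channel("EDA", 4, 400, function(ts) 0.5 + 0 * ts, t0)
  f <- eda_features(const, t0 + 350, window_s = 300)
  expect_equal(unname(f), c(0.5, 0, 0))

  # linear ramp 0.1 -> 0.9 uS over 300 s: mAmp = mid, Slope = 0.8/300
  ramp <- make_channel("EDA", 4, 300, function(ts) 0.1 + (0.8 / 300) * ts, t0)
  f <- eda_features(ramp, t0 + 300, window_s = 300)
  expect_equal(unname(f["mAmp"]), 0.5, tolerance = 1e-2)
  expect_equal(unname(f["Slope"]), 0.8 / 300, tolerance = 1e-6)

  # mAmp scales linearly with the signal; Events is shift-invariant
  set.seed(5)
  noisy_vals <- 0.5 + cumsum(rnorm(1600, sd = 0.01))
  noisy <- channel_series("EDA", t0, 4, noisy_vals)
  shifted <- channel_series("EDA", t0, 4, noisy_vals + 5)
  scaled <- channel_series("EDA", t0, 4, noisy_vals * 3)
  fn <- eda_features(noisy, t0 + 350)
  expect_equal(unname(eda_features(scaled, t0 + 350)["mAmp"]),
               unname(fn["mAmp"]) * 3)
  expect_equal(unname(eda_features(shifted, t0 + 350)["Events"]),
               unname(fn["Events"]))
})

test_that("BVP features match the sine-wave closed form", {
  const <- make_channel("BVP", 64, 400, function(ts) -2 + 0 * ts, t0)
  expect_equal(unname(bvp_features(const, t0 + 350)), c(2, -2, -2))

  # amplitude-A sine over whole periods: mean|x| -> 2A/pi
  A <- 1.7
  sine <- make_channel("BVP", 64, 300, function(ts) A * sin(2 * pi * ts), t0)
  f <- bvp_features(sine, t0 + 300, window_s = 300)
  expect_equal(unname(f["BVPmeanAbs"]), 2 * A / pi, tolerance = 0.01)
  expect_equal(unname(f["BVPmin"]), -A, tolerance = 1e-3)
  expect_equal(unname(f["BVPmax"]), A, tolerance = 1e-3)
  expect_lte(f["BVPmin"], f["BVPmax"])
})

test_that("temperature slope recovers exact and noisy linear trends", {
  flat <- make_channel("TEMP", 4, 300, function(ts) 33 + 0 * ts, t0)
  expect_equal(unname(temp_slope(flat, t0 + 200)), 0)

  lin <- make_channel("TEMP", 4, 300, function(ts) 33 + 0.001 * ts, t0)
  expect_equal(unname(temp_slope(lin, t0 + 200, 60)), 0.001, tolerance = 1e-10)

  # noisy line: OLS slope within 3 standard errors of truth
  set.seed(6)
  n <- 240; sdn <- 0.01; slope <- 0.002
  noisy <- make_channel("TEMP", 4, 60, function(ts) 33 + slope * ts, t0)
  noisy$values <- noisy$values + rnorm(n, sd = sdn)
  tt <- (seq_len(n) - 1) / 4
  se <- sdn / sqrt(sum((tt - mean(tt))^2))
  expect_lt(abs(temp_slope(noisy, t0 + 60, 60) - slope), 3 * se)
})

test_that("assembled series has the right shape and matches per-family ops", {
  rec <- make_recording(dur_s = 3600)
  fs <- assemble_feature_series(rec)
  expect_equal(nrow(fs$matrix), 3600)
  expect_equal(colnames(fs$matrix), ppactiv_features)
  expect_false(any(fs$valid[1:299]))  # warm-up rows masked
  expect_true(any(fs$valid))

  for (t in c(t0 + 400, t0 + 1833, t0 + 3600)) {
    row <- fs$matrix[match(t, fs$timestamps), ]
    ref <- c(hrv_features(rec$ibi, t), eda_features(rec$channels$EDA, t),
             bvp_features(rec$channels$BVP, t),
             temp_slope(rec$channels$TEMP, t))
    expect_equal(unname(row), unname(ref), tolerance = 1e-8)
  }

  rec$channels$EDA <- NULL
  expect_error(assemble_feature_series(rec), "EDA", class = "ppactiv_config")
})

test_that("features are causal: truncating the future changes nothing", {
  rec <- make_recording(dur_s = 1200)
  fs <- assemble_feature_series(rec)
  t_cut <- t0 + 800
  rec2 <- rec
  rec2$session_span <- c(t0, t_cut)
  for (ch in names(rec2$channels)) {
    cs <- rec2$channels[[ch]]
    keep <- channel_times(cs) <= t_cut
    rec2$channels[[ch]] <- channel_series(cs$name, cs$start_time, cs$rate_hz,
                                          cs$values[keep])
  }
  keep <- rec2$ibi$offsets <= t_cut - t0
  rec2$ibi <- ibi_series(t0, rec2$ibi$offsets[keep], rec2$ibi$rr[keep])
  fs2 <- assemble_feature_series(rec2)
  upto <- fs$timestamps <= t_cut
  expect_equal(fs$matrix[upto, ], fs2$matrix, tolerance = 1e-12)
})
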