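small_spec <- function(...) {
  args <- utils::modifyList(list(n_traders = 3, days_per_trader = 1,
                                 session_hours = 1.5, seed = 77,
                                 coupling = list()),
                            list(...))
  do.call(cohort_spec, args)
}

test_that("generation is bit-reproducible under the master seed", {
  sp <- small_spec()
  r1 <- generate_physiology(sp, 1, 1)
  r2 <- generate_physiology(sp, 1, 1)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  m1 <- generate_markets(sp, sp$start_date)
  m2 <- generate_markets(sp, sp$start_date)
  expect_identical(m1, m2)
  t1 <- generate_transactions(sp, 2, 1)
  t2 <- generate_transactions(sp, 2, 1)
  expect_identical(t1, t2)
  # different seed, different data
  r3 <- generate_physiology(small_spec(seed = 78), 1, 1)
  expect_false(identical(r1$ibi$rr, r3$ibi$rr))
})

test_that("recordings respect the device contract", {
  sp <- small_spec()
  rec <- generate_physiology(sp, 1, 1)
  expect_setequal(names(rec$channels),
                  c("BVP", "EDA", "TEMP", "HR", "ACC_X", "ACC_Y", "ACC_Z"))
  expect_equal(rec$channels$BVP$rate_hz, 64)
  expect_equal(rec$channels$EDA$rate_hz, 4)
  D <- diff(rec$session_span)
  expect_equal(length(rec$channels$EDA$values), D * 4)
  # IBI invariants hold by construction
  expect_true(all(diff(rec$ibi$offsets) > 0))
  expect_true(all(rec$ibi$rr > 0))
  expect_lte(max(rec$ibi$offsets), D)
})

test_that("overlapping planted episodes are a specification error", {
  sp <- small_spec()
  win <- ppactiv:::session_window(sp, 1, 1)
  ep <- data.frame(start = win[1] + c(600, 800), end = win[1] + c(900, 1100),
                   magnitude = 1)
  expect_error(generate_physiology(sp, 1, 1, ep), class = "ppactiv_spec")
})

test_that("planted episodes perturb the physiology in the stated directions", {
  sp <- small_spec()
  win <- ppactiv:::session_window(sp, 1, 1)
  ep <- data.frame(start = win[1] + 1800, end = win[1] + 2800, magnitude = 1)
  base <- generate_physiology(sp, 1, 1)
  pert <- generate_physiology(sp, 1, 1, ep)
  inside <- function(x, off) x > 1800 + 60 & x < 2800 - 60
  # heart period drops ~10% inside the episode
  b_in <- base$ibi$rr[inside(base$ibi$offsets)]
  p_in <- pert$ibi$rr[inside(pert$ibi$offsets)]
  expect_lt(mean(p_in), mean(b_in) * 0.95)
  # SCR rate rises: more detected events inside the episode window
  ev_b <- detect_scr_events(base$channels$EDA)
  ev_p <- detect_scr_events(pert$channels$EDA)
  cnt <- function(ev, s) sum(ev$peak_s - s > 1800 & ev$peak_s - s < 2800)
  expect_gt(cnt(ev_p, win[1]), cnt(ev_b, win[1]))
})

test_that("transaction counts follow the configured Poisson rate", {
  rates <- sapply(1:60, function(s) {
    sp <- cohort_spec(n_traders = 1, days_per_trader = 1, seed = s,
                      coupling = list())
    nrow(generate_transactions(sp, 1, 1)$log)
  })
  # mean count within 3 SE of 8 over 60 seeded days
  expect_lt(abs(mean(rates) - 8), 3 * sqrt(8 / 60))
})

test_that("every transaction plants its bumps exactly once", {
  sp <- cohort_spec(n_traders = 1, days_per_trader = 1, seed = 5,
                    coupling = list())
  tx <- generate_transactions(sp, 1, 1)
  n <- nrow(tx$log)
  expect_gt(n, 0)
  win <- ppactiv:::session_window(sp, 1, 1)
  # one post bump per transaction unless clipped below 60 s of support
  expected_post <- sum(pmin(tx$log$timestamp + 25 * 60, win[2]) -
                         pmax(tx$log$timestamp + 15 * 60, win[1]) >= 60)
  expect_equal(sum(tx$bumps$source == "post_txn"), expected_post)
  expect_lte(sum(tx$bumps$source == "pre_txn"), n)
})

test_that("uncoupled market increments look like white noise", {
  sp <- small_spec()
  mk <- generate_markets(sp, sp$start_date)
  expect_length(mk$drivers, 0)
  for (ix in c("CDS_IG", "VIX")) {
    incr <- diff(mk$markets[[ix]]$values)
    bt <- Box.test(incr, lag = 10, type = "Ljung-Box")
    expect_gt(bt$p.value, 0.001)
  }
  expect_equal(diff(mk$markets[[1]]$timestamps), rep(60, 89))
})

test_that("coupled markets lead the driver by the configured lag", {
  sp <- cohort_spec(n_traders = 2, days_per_trader = 1, session_hours = 6.5,
                    seed = 9,
                    coupling = list(list(index_name = "CDS_IG", lag_min = 3,
                                         strength = 1.5,
                                         trader_ids = "T01")))
  mk <- generate_markets(sp, sp$start_date)
  drv <- mk$drivers$CDS_IG
  vals <- mk$markets$CDS_IG$values
  incr <- c(vals[1] - 100, diff(vals))  # raw random-walk increments
  n <- length(drv)
  # increment at minute m carries driver at m + lag: cross-correlation peaks
  # at the injection offset
  cc <- sapply(0:6, function(k)
    cor(incr[seq_len(n - k)], drv[(1 + k):n]))
  expect_equal(which.max(cc) - 1, 3)
})

test_that("the cohort plan yields the study panel sizes", {
  sp <- cohort_spec(seed = 1)
  expect_equal(nrow(cohort_plan(sp)), 275)      # 55 traders x 5 days
  spd <- cohort_spec(seed = 1, dropout_rate = 0.12)
  expect_equal(nrow(cohort_plan(spd)), 242)     # the study's panel size
})

test_that("a small cohort materializes consistently with its ground truth", {
  sp <- small_spec(n_traders = 2)
  co <- generate_cohort(sp)
  expect_length(co$recordings, 2)
  expect_equal(nrow(co$profiles), 2)
  expect_s3_class(co$truth, "ground_truth")
  expect_equal(nrow(co$truth$uplift), 2)
  expect_true(all(co$truth$uplift$ramp >= 0))
  # cohort write/read round trip, ground truth included
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_length(back$recordings, 2)
  expect_equal(back$profiles$experience_years, co$profiles$experience_years)
  expect_s3_class(back$truth, "ground_truth")
  expect_equal(back$truth$coefficients$experience,
               sp$coefficients$experience)
  r0 <- co$recordings[[1]]
  r1 <- back$recordings[[paste0(r0$trader_id, "_1")]]
  expect_equal(r1$channels$EDA$values, r0$channels$EDA$values,
               tolerance = 1e-6)
  expect_equal(r1$ibi$rr, r0$ibi$rr, tolerance = 1e-8)
})

test_that("planted attribution effects are recovered from the full chain", {
  # coupling-free cohort so the attribution channel is isolated; one day per
  # trader so every panel row is an independent cluster and the classical SE
  # is honest. The planted negative experience effect must be recovered
  # within 2 SE.
  sp <- cohort_spec(n_traders = 55, days_per_trader = 1, seed = 66,
                    coupling = list())
  co <- generate_cohort(sp, materialize = FALSE)
  summ <- list()
  for (r in seq_len(nrow(co$plan))) {
    inp <- ppactiv:::trader_day_inputs(sp, co$plan$trader[r], co$plan$day[r],
                                       co$profiles, sp$coefficients, list())
    rec <- generate_physiology(sp, co$plan$trader[r], co$plan$day[r],
                               inp$episodes, inp$drive)
    act <- activation_series(assemble_feature_series(rec))
    summ[[r]] <- summarize_day(act)
  }
  summ <- do.call(rbind, summ)
  ds <- build_dataset(summ, co$profiles, co$transactions, markets = NULL)
  fit <- fit_attribution(ds)
  co_t <- fit$coefficients
  i <- match("experience_years", co_t$term)
  theta <- sp$coefficients$experience
  expect_lt(abs(co_t$estimate[i] - theta), 2 * co_t$std.error[i])
})

test_that("a planted episode is recovered by the activation pipeline", {
  # one 10-minute magnitude-1 episode in an otherwise baseline day: detected
  # mild episodes must overlap it (Jaccard >= 0.5) in most seeded runs
  hits <- 0; runs <- 10
  for (s in seq_len(runs)) {
    sp <- cohort_spec(n_traders = 1, days_per_trader = 1, session_hours = 3,
                      seed = 1000 + s, coupling = list())
    win <- ppactiv:::session_window(sp, 1, 1)
    ep <- data.frame(start = win[1] + 6000, end = win[1] + 6600,
                     magnitude = 1)
    rec <- generate_physiology(sp, 1, 1, ep)
    act <- activation_series(assemble_feature_series(rec))
    det <- label_episodes(act)
    det <- det[det$level == "mild", ]
    if (!nrow(det)) next
    inter <- sum(pmax(0, pmin(det$end, ep$end) - pmax(det$start, ep$start)))
    un <- (ep$end - ep$start) + sum(det$end - det$start) - inter
    if (inter / un >= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
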