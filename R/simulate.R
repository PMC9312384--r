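# Seeded synthetic trader cohorts with planted ground truth.
#
# The signal models are deliberately simple -- an AR(1) heart-period process,
# Poisson skin-conductance responses with exponential decay, a pulse-rate
# oscillation for BVP, random-walk temperature and market indices -- because
# the generator exists to validate the ANALYSIS pipeline against a known
# truth, not to reproduce physiological realism. Every trader-day draws from
# an independent sub-seed mixed from the master seed, so any subset of the
# cohort can be regenerated bit-identically.

#' Specification of a synthetic trader cohort
#'
#' Defaults mirror the study conditions: 55 traders observed over five
#' trading days (6.5-hour sessions), six-channel wristband recordings at the
#' public device rates (BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz, HR 1 Hz, ACC 32 Hz),
#' eight market indices, about eight transactions per trader-day with
#' log-normal dollar amounts (median $1M), post-transaction activation bumps
#' peaking 15-25 minutes after the trade plus a smaller pre-transaction bump,
#' market-to-activation coupling on the credit-default-swap index for a
#' subset of traders, and planted attribution coefficients (notably a
#' negative experience effect of -0.02 per year of experience, on the
#' average-activation scale).
#'
#' @param n_traders number of traders (default 55).
#' @param days_per_trader trading days per trader (default 5).
#' @param session_hours session length in hours (default 6.5).
#' @param seed master seed; fully determines the cohort.
#' @param dropout_rate fraction of trader-days dropped from the panel (the
#'   study's device failures); `floor(rate * n)` trader-days are removed, so
#'   e.g. 0.12 turns the 275 trader-days of the default cohort into 242.
#' @param divisions business-division labels.
#' @param rates device sampling rates (Hz) per channel family.
#' @param transactions list: `rate_per_day`, `amount_meanlog`, `amount_sdlog`.
#' @param bumps list: post-/pre-transaction activation bump windows (minutes
#'   relative to the trade) and amplitudes (episode-magnitude units), and
#'   `enabled`.
#' @param coupling list of couplings, each
#'   `list(index_name, lag_min, strength, n_traders)`: the index leads the
#'   activation of `n_traders` randomly chosen traders by `lag_min` minutes.
#' @param indices market-index labels.
#' @param coefficients planted attribution effects on the average-activation
#'   scale: `intercept_uplift`, `experience` (per year), `gender_male`,
#'   `division` (named offsets), `amt` (per $1M of mean trade size), `numT`
#'   (per transaction), `resid_sd` (trader-day noise).
#' @param start_date first trading day.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_traders = 55, days_per_trader = 5,
                        session_hours = 6.5, seed = 1, dropout_rate = 0,
                        divisions = c("commodities", "equities",
                                      "fixed_income", "fx"),
                        rates = list(bvp = 64, eda = 4, temp = 4, hr = 1,
                                     acc = 32),
                        transactions = list(rate_per_day = 8,
                                            amount_meanlog = log(1e6),
                                            amount_sdlog = 1),
                        bumps = list(enabled = TRUE,
                                     post_window_min = c(15, 25),
                                     post_amplitude = 0.6,
                                     pre_window_min = c(-5, 0),
                                     pre_amplitude = 0.3),
                        coupling = list(list(index_name = "CDS_IG",
                                             lag_min = 3, strength = 1.5,
                                             n_traders = 22)),
                        indices = c("CDS_IG", "CDS_HY", "USD_Index",
                                    "UST_10Y", "SP500_Emini", "UST_5Y",
                                    "Crude_Oil", "VIX"),
                        coefficients = list(intercept_uplift = 2,
                                            experience = -0.02,
                                            gender_male = -0.02,
                                            division = c(commodities = 0.05,
                                                         equities = 0,
                                                         fixed_income = 0.15,
                                                         fx = -0.05),
                                            amt = 0.02, numT = 4e-5,
                                            resid_sd = 0.05),
                        start_date = as.Date("2020-03-02")) {
  stopifnot(n_traders >= 1, days_per_trader >= 1, session_hours > 0,
            all(unlist(rates) > 0))
  structure(list(
    n_traders = n_traders, days_per_trader = days_per_trader,
    session_hours = session_hours, seed = seed, dropout_rate = dropout_rate,
    divisions = divisions, rates = rates, transactions = transactions,
    bumps = bumps, coupling = coupling, indices = indices,
    coefficients = coefficients, start_date = as.Date(start_date),
    stagger_weeks = TRUE,
    session_start_hour = 9.5, market_step_sd = 1,
    coupling_phi = 0.9,          # minute-scale persistence of the driver
    phys_coupling_scale = 1.5,   # physiological forcing per unit driver
    # mean-activation response to the day-long arousal drift that delivers
    # the planted attribution effects: measured once from this generator
    # (16 trader-days per anchor, transaction bumps present; see vignette)
    ramp_response = list(
      ramp = c(0, 0.15, 0.3, 0.45, 0.6, 0.8, 1.0, 1.3, 1.7, 2.2, 3.0),
      uplift = c(0, 0.393, 0.776, 1.220, 1.783, 2.466, 3.102, 3.962,
                 5.037, 6.294, 7.792))),
    class = "cohort_spec")
}

# traders are recorded in staggered weeks (one trader per calendar week by
# default), so day-level market covariates vary across the panel instead of
# collapsing onto a handful of shared dates
cohort_date <- function(spec, trader, day_index) {
  off <- if (isTRUE(spec$stagger_weeks)) (trader_index(trader) - 1) * 7 else 0
  spec$start_date + off + (day_index - 1)
}

session_window <- function(spec, trader, day_index) {
  day <- cohort_date(spec, trader, day_index)
  S <- as.numeric(as.POSIXct(paste(day, "00:00:00"), tz = "UTC")) +
    spec$session_start_hour * 3600
  c(S, S + spec$session_hours * 3600)
}

# ramped episode envelope on the 1 Hz grid t = S..E
episode_envelope <- function(tgrid, episodes, ramp_s = 30) {
  g <- numeric(length(tgrid))
  if (is.null(episodes) || !nrow(episodes)) return(g)
  ep <- episodes[order(episodes$start), ]
  if (nrow(ep) > 1 && any(ep$start[-1] <= ep$end[-nrow(ep)]))
    stop_ppactiv("overlapping planted episodes", class = "ppactiv_spec")
  for (i in seq_len(nrow(ep))) {
    w <- pmax(0, pmin(1, (tgrid - ep$start[i]) / ramp_s,
                      (ep$end[i] - tgrid) / ramp_s))
    g <- g + ep$magnitude[i] * w
  }
  g
}

# union of possibly-overlapping intervals, keeping the max magnitude
merge_episodes <- function(ep) {
  if (!nrow(ep)) return(ep)
  ep <- ep[order(ep$start), ]
  out <- ep[1, , drop = FALSE]
  for (i in seq_len(nrow(ep))[-1]) {
    j <- nrow(out)
    if (ep$start[i] <= out$end[j] + 1) {
      out$end[j] <- max(out$end[j], ep$end[i])
      out$magnitude[j] <- max(out$magnitude[j], ep$magnitude[i])
    } else {
      out <- rbind(out, ep[i, ])
    }
  }
  out
}

#' Generate one trader-day of synthetic physiology
#'
#' Baseline model: heart period is a mean-reverting AR(1) at beat scale
#' (mean 0.85 s, stationary sd 0.05 s, phi = 0.95); EDA is a slow tonic
#' random walk plus phasic skin-conductance responses from a Poisson process
#' (2/min at baseline), each rising 0.1-0.5 uS within ~2 s and decaying
#' exponentially (tau = 40 s); BVP is a unit-amplitude oscillation at the
#' instantaneous heart rate with multiplicative amplitude noise; TEMP is a
#' slow random walk (0.002 degC/s); the accelerometer axes are small Gaussian
#' noise. During planted episodes (30 s onset/offset ramps, scaled by
#' episode magnitude): heart-period mean -10% and variability -30%, SCR rate
#' x4, BVP amplitude x1.5, TEMP slope +0.003 degC/s.
#'
#' @param spec a [cohort_spec()].
#' @param trader trader index (1-based) or id like `"T07"`.
#' @param day day index (1-based).
#' @param episodes optional data.frame `(start, end, magnitude)` in epoch
#'   seconds; overlapping episodes are an error.
#' @param drive optional non-negative per-minute forcing vector (the
#'   market-coupling drive), added to the episode envelope.
#' @return a [physio_recording()].
#' @export
generate_physiology <- function(spec, trader, day, episodes = NULL,
                                drive = NULL) {
  ti <- trader_index(trader)
  win <- session_window(spec, ti, day)
  S <- win[1]; E <- win[2]; D <- E - S
  set.seed(mix_seed(spec$seed, ti, day, 1))
  tgrid <- seq(S, E)
  g <- episode_envelope(tgrid, episodes)
  if (!is.null(drive)) {
    # negative forcing = calmer than baseline; channel clamps below guard
    # the physical ranges
    g <- g + rep(drive, each = 60, length.out = length(tgrid))
  }
  g_at <- function(times) g[pmin(pmax(floor(times - S) + 1, 1), length(g))]

  # --- inter-beat stream ---------------------------------------------------
  phi <- 0.95; h0 <- 0.85; hsd <- 0.05
  nb <- ceiling(D / 0.55) + 10
  x <- as.numeric(stats::filter(rnorm(nb, sd = hsd * sqrt(1 - phi^2)), phi,
                                method = "recursive"))
  bt0 <- S + (seq_len(nb)) * h0
  gk <- g_at(bt0)
  h <- pmax(h0 * pmax(1 - 0.10 * gk, 0.5) + x * pmax(1 - 0.30 * gk, 0.1), 0.3)
  bt <- S + cumsum(h)
  keep <- bt <= E
  ibi <- ibi_series(S, bt[keep] - S, h[keep])

  # --- EDA -----------------------------------------------------------------
  r_eda <- spec$rates$eda
  n4 <- as.integer(D * r_eda)
  ts4 <- S + (seq_len(n4) - 1) / r_eda
  eda <- 0.4 + cumsum(rnorm(n4, sd = 5e-4))
  base_rate <- 2 / 60                       # SCRs per second
  gmax <- max(g, 0)
  rate_max <- base_rate * (1 + 3 * gmax)
  ncand <- rpois(1, rate_max * D)
  cand <- sort(runif(ncand, S, E))
  acc <- runif(ncand) < pmax(1 + 3 * g_at(cand), 0) / (1 + 3 * gmax)
  scr_t <- cand[acc]
  scr_a <- runif(length(scr_t), 0.1, 0.5)
  tau <- 40; rise_s <- 1.5
  klen <- as.integer((rise_s + 6 * tau) * r_eda)
  krel <- (seq_len(klen) - 1) / r_eda
  kern <- ifelse(krel < rise_s, krel / rise_s, exp(-(krel - rise_s) / tau))
  for (e in seq_along(scr_t)) {
    i0 <- as.integer(floor((scr_t[e] - S) * r_eda)) + 1L
    ii <- i0:min(i0 + klen - 1L, n4)
    eda[ii] <- eda[ii] + scr_a[e] * kern[seq_along(ii)]
  }

  # --- BVP -----------------------------------------------------------------
  r_bvp <- spec$rates$bvp
  n64 <- as.integer(D * r_bvp)
  ts_rel <- (seq_len(n64) - 1) / r_bvp
  h_interp <- approx(bt - S, h, xout = ts_rel, rule = 2)$y
  phase <- 2 * pi * cumsum((1 / r_bvp) / h_interp)
  amp <- exp(0.1 * rnorm(n64)) * pmax(1 + 0.5 * g_at(S + ts_rel), 0.05)
  bvp <- amp * sin(phase)

  # --- TEMP ----------------------------------------------------------------
  r_temp <- spec$rates$temp
  nt <- as.integer(D * r_temp)
  g4 <- g_at(S + (seq_len(nt) - 1) / r_temp)
  temp <- 33 + cumsum(rnorm(nt, sd = 0.002 / sqrt(r_temp)) + 0.003 * g4 / r_temp)

  # --- ACC, HR -------------------------------------------------------------
  r_acc <- spec$rates$acc
  na_ <- as.integer(D * r_acc)
  hr1 <- 60 / approx(bt - S, h, xout = tgrid - S, rule = 2)$y +
    rnorm(length(tgrid), sd = 0.5)

  physio_recording(
    trader_id = trader_id_of(ti), day = cohort_date(spec, ti, day),
    channels = list(
      BVP = channel_series("BVP", S, r_bvp, bvp),
      EDA = channel_series("EDA", S, r_eda, eda),
      TEMP = channel_series("TEMP", S, r_temp, temp),
      HR = channel_series("HR", S, spec$rates$hr, hr1),
      ACC_X = channel_series("ACC_X", S, r_acc, rnorm(na_, 0, 0.02)),
      ACC_Y = channel_series("ACC_Y", S, r_acc, rnorm(na_, 0, 0.02)),
      ACC_Z = channel_series("ACC_Z", S, r_acc, rnorm(na_, 1, 0.02))),
    ibi = ibi, session_span = c(S, E))
}

trader_index <- function(trader) {
  if (is.character(trader)) as.integer(sub("^T", "", trader)) else as.integer(trader)
}
trader_id_of <- function(i) sprintf("T%02d", i)

#' Generate one day's market-index series
#'
#' Each index is a Gaussian random walk at 1-minute steps over the session.
#' For every coupling entry one non-negative driver series is drawn for the
#' index and injected into its increments `lag_min` minutes EARLY, so the
#' market series leads the activation of the coupled traders (the Granger
#' direction the scan tests). The drivers are returned so the physiological
#' forcing of the coupled traders can be built from the same realization.
#'
#' @param spec a [cohort_spec()].
#' @param date the calendar trading day (`Date`); the seed derives from it,
#'   so every trader active on that day sees the same market realization.
#' @return list `(markets, drivers)`: named list of [market_series()] and a
#'   named list of per-minute driver vectors (one per coupled index).
#' @export
generate_markets <- function(spec, date) {
  date <- as.Date(date)
  S <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC")) +
    spec$session_start_hour * 3600
  n_min <- as.integer(spec$session_hours * 60)
  ts <- S + 60 * (seq_len(n_min) - 1)
  set.seed(mix_seed(spec$seed, 0, as.integer(date), 2))
  coupled <- vapply(spec$coupling, function(cc) cc$index_name, character(1))
  drivers <- list()
  markets <- list()
  for (ix in spec$indices) {
    incr <- rnorm(n_min, sd = spec$market_step_sd)
    ci <- match(ix, coupled)
    if (!is.na(ci)) {
      cc <- spec$coupling[[ci]]
      if (cc$lag_min < 1)
        stop_ppactiv("coupling lag must be >= 1 minute", class = "ppactiv_spec")
      phi <- spec$coupling_phi
      lat <- as.numeric(stats::filter(rnorm(n_min, sd = sqrt(1 - phi^2)),
                                      phi, method = "recursive"))
      drv <- pmax(lat, 0)                 # rectified: activation responds to
      drivers[[ix]] <- drv                # magnitude, market to the same sign
      lag <- cc$lag_min
      incr[seq_len(n_min - lag)] <- incr[seq_len(n_min - lag)] +
        cc$strength * spec$market_step_sd * (drv[(1 + lag):n_min] - mean(drv))
    }
    markets[[ix]] <- market_series(ix, ts, 100 + cumsum(incr))
  }
  list(markets = markets, drivers = drivers)
}

#' Generate one trader-day's transactions and their activation bumps
#'
#' Transaction times follow a Poisson process over the session (default mean
#' 8/day) with log-normal dollar amounts (median $1M). When bumps are
#' enabled, each transaction plants a post-transaction activation episode in
#' the configured window (default +15..+25 min) and a smaller pre-transaction
#' episode (default -5..0 min), recorded one-for-one in the ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param trader trader index or id.
#' @param day day index.
#' @return list `(log, bumps)`: a [transaction_log()] and the bump episode
#'   data.frame `(start, end, magnitude, source)`.
#' @export
generate_transactions <- function(spec, trader, day) {
  ti <- trader_index(trader)
  win <- session_window(spec, ti, day)
  set.seed(mix_seed(spec$seed, ti, day, 3))
  n <- rpois(1, spec$transactions$rate_per_day)
  times <- sort(runif(n, win[1], win[2]))
  amounts <- rlnorm(n, spec$transactions$amount_meanlog,
                    spec$transactions$amount_sdlog)
  log <- transaction_log(rep(trader_id_of(ti), n), times, amounts)
  bumps <- data.frame(start = numeric(), end = numeric(),
                      magnitude = numeric(), source = character())
  if (isTRUE(spec$bumps$enabled) && n > 0) {
    mk <- function(l, w, a, src) {
      s <- pmax(l + w[1] * 60, win[1]); e <- pmin(l + w[2] * 60, win[2])
      if (e - s < 60) return(NULL)
      data.frame(start = s, end = e, magnitude = a, source = src)
    }
    for (l in times) {
      bumps <- rbind(bumps,
                     mk(l, spec$bumps$post_window_min,
                        spec$bumps$post_amplitude, "post_txn"),
                     mk(l, spec$bumps$pre_window_min,
                        spec$bumps$pre_amplitude, "pre_txn"))
    }
  }
  list(log = log, bumps = bumps)
}

# The planted mean-activation differences are delivered by a day-long linear
# drift in the arousal forcing (0 at session start, `ramp` at close): the
# expanding-window baseline lags a trend persistently, so unlike transient
# episodes -- which the adaptive covariance absorbs almost completely -- a
# drift raises the day's mean activation monotonically in the slope. The
# required slope for a target uplift is read off the generator's measured
# response curve by interpolation.
ramp_of_uplift <- function(spec, U) {
  rr <- spec$ramp_response
  approx(rr$uplift, rr$ramp, xout = max(U, 0), rule = 2)$y
}

#' The planned trader-days of a cohort (after dropout)
#'
#' @param spec a [cohort_spec()].
#' @return data.frame `(trader_id, trader, day, date)` of the kept
#'   trader-days; with `dropout_rate` r, exactly
#'   `floor(r * n_traders * days_per_trader)` trader-days are removed
#'   (seeded).
#' @export
cohort_plan <- function(spec) {
  plan <- expand.grid(trader = seq_len(spec$n_traders),
                      day = seq_len(spec$days_per_trader))
  plan <- plan[order(plan$trader, plan$day), ]
  plan$trader_id <- trader_id_of(plan$trader)
  plan$date <- cohort_date(spec, plan$trader, plan$day)
  n_drop <- floor(spec$dropout_rate * nrow(plan))
  if (n_drop > 0) {
    set.seed(mix_seed(spec$seed, 0, 0, 4))
    plan <- plan[-sample.int(nrow(plan), n_drop), ]
  }
  rownames(plan) <- NULL
  plan[c("trader_id", "trader", "day", "date")]
}

# everything about one trader-day needed to generate it: transactions, planted
# episodes (attribution schedule + transaction bumps, overlaps merged),
# coupling drive, and the attribution target
trader_day_inputs <- function(spec, trader, day, profiles, truth_coefs,
                              drivers) {
  ti <- trader_index(trader)
  win <- session_window(spec, ti, day)
  tx <- generate_transactions(spec, ti, day)
  prof <- profiles[profiles$trader_id == trader_id_of(ti), ]
  cf <- truth_coefs
  amt <- if (nrow(tx$log)) mean(tx$log$amount_usd) / 1e6 else 0
  numT <- nrow(tx$log)
  set.seed(mix_seed(spec$seed, ti, day, 5))
  U <- cf$intercept_uplift +
    cf$experience * prof$experience_years +
    cf$gender_male * (prof$gender == "male") +
    cf$division[[prof$division]] +
    cf$amt * amt + cf$numT * numT +
    rnorm(1, sd = cf$resid_sd)
  det <- cf$intercept_uplift + cf$experience * prof$experience_years +
    cf$gender_male * (prof$gender == "male") + cf$division[[prof$division]]
  if (det < 0)
    stop_ppactiv("infeasible planted effects: negative activation uplift (",
                 signif(det, 3), ") for trader ", prof$trader_id,
                 class = "ppactiv_spec")
  ep <- tx$bumps[order(tx$bumps$start), c("start", "end", "magnitude")]
  ep <- merge_episodes(ep)
  n_min <- as.integer((win[2] - win[1]) / 60)
  ramp <- ramp_of_uplift(spec, U)
  drive <- ramp * (seq_len(n_min) - 0.5) / n_min
  for (cc in spec$coupling) {
    if (trader_id_of(ti) %in% cc$trader_ids %||% character()) {
      drv <- drivers[[cc$index_name]]
      if (!is.null(drv))  # centered: minute-scale signal without a day-mean
        drive <- drive + spec$phys_coupling_scale * cc$strength *
          (drv - mean(drv))
    }
  }
  list(transactions = tx$log, episodes = ep, bumps = tx$bumps, drive = drive,
       target_uplift = U, ramp = ramp, win = win)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws trader covariates (experience uniform on 1-25 years, divisions
#' multinomial, gender balanced), assigns the coupled traders, simulates the
#' markets, transactions and (optionally) the physiological recordings of
#' every planned trader-day, and returns the ground truth that fully
#' determines the cohort: planted episodes, coupling assignments, planted
#' attribution coefficients and the bump specification.
#'
#' @param spec a [cohort_spec()].
#' @param materialize generate the raw recordings (`TRUE`, default) or only
#'   the plan, markets, transactions, profiles and ground truth (`FALSE`;
#'   use [generate_physiology()] with the episodes in the truth to realize a
#'   given trader-day). Large cohorts hold gigabytes of raw samples, so the
#'   pipeline materializes one trader-day at a time.
#' @return list with `recordings` (named `"T01_1"` etc., or `NULL`),
#'   `markets` (per day, named list of [market_series()]), `transactions`,
#'   `profiles`, `truth` (class `ground_truth`), `plan`, `spec`.
#' @export
generate_cohort <- function(spec, materialize = TRUE) {
  set.seed(mix_seed(spec$seed, 0, 0, 0))
  profiles <- trader_profiles(
    trader_id = trader_id_of(seq_len(spec$n_traders)),
    gender = sample(c("female", "male"), spec$n_traders, replace = TRUE),
    experience_years = runif(spec$n_traders, 1, 25),
    division = sample(spec$divisions, spec$n_traders, replace = TRUE))
  for (i in seq_along(spec$coupling)) {
    cc <- spec$coupling[[i]]
    if (is.null(cc$trader_ids)) {
      k <- min(cc$n_traders %||% 0, spec$n_traders)
      spec$coupling[[i]]$trader_ids <-
        trader_id_of(sort(sample.int(spec$n_traders, k)))
    }
  }
  plan <- cohort_plan(spec)
  dates <- sort(unique(plan$date))
  mkts <- lapply(dates, function(dt) generate_markets(spec, dt))
  names(mkts) <- as.character(dates)
  markets <- lapply(mkts, `[[`, "markets")
  recs <- if (materialize) vector("list", nrow(plan)) else NULL
  tx_all <- list(); ep_all <- list(); up_all <- list()
  for (r in seq_len(nrow(plan))) {
    ti <- plan$trader[r]; dd <- plan$day[r]
    inp <- trader_day_inputs(spec, ti, dd, profiles, spec$coefficients,
                             mkts[[as.character(plan$date[r])]]$drivers)
    tx_all[[r]] <- inp$transactions
    up_all[[r]] <- data.frame(trader_id = plan$trader_id[r], day = dd,
                              target_uplift = inp$target_uplift,
                              ramp = inp$ramp)
    if (nrow(inp$episodes))
      ep_all[[r]] <- data.frame(trader_id = plan$trader_id[r], day = dd,
                                inp$episodes)
    if (materialize) {
      recs[[r]] <- generate_physiology(spec, ti, dd, inp$episodes, inp$drive)
      names(recs)[r] <- paste0(plan$trader_id[r], "_", dd)
    }
  }
  transactions <- do.call(rbind, tx_all)
  class(transactions) <- c("transaction_log", "data.frame")
  coup <- do.call(rbind, lapply(spec$coupling, function(cc)
    if (length(cc$trader_ids)) data.frame(trader_id = cc$trader_ids,
                                          index_name = cc$index_name,
                                          lag_min = cc$lag_min,
                                          strength = cc$strength)))
  truth <- structure(list(
    seed = spec$seed,
    episodes = if (length(ep_all)) do.call(rbind, ep_all) else
      data.frame(trader_id = character(), day = integer(), start = numeric(),
                 end = numeric(), magnitude = numeric()),
    coupling = coup %||% data.frame(trader_id = character(),
                                    index_name = character(),
                                    lag_min = numeric(), strength = numeric()),
    coefficients = spec$coefficients,
    uplift = do.call(rbind, up_all),
    bump_spec = spec$bumps),
    class = "ground_truth")
  list(recordings = recs, markets = markets, transactions = transactions,
       profiles = profiles, truth = truth, plan = plan, spec = spec)
}

#' Write a cohort directory tree
#'
#' Lays out `data/<trader>/day<d>/{BVP,EDA,TEMP,HR,ACC_X,ACC_Y,ACC_Z,IBI}.csv`
#' plus `markets.csv`, `transactions.csv`, `profiles.csv` and
#' `ground_truth.json`, mirroring the reader layout. Intended for small
#' cohorts (raw channels are large).
#'
#' @param cohort output of [generate_cohort()] with `materialize = TRUE`.
#' @param dir destination directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$recordings))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$recordings)) {
    rec <- cohort$recordings[[nm]]
    parts <- strsplit(nm, "_")[[1]]
    d <- file.path(dir, "data", parts[1], paste0("day", parts[2]))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (ch in names(rec$channels))
      write_channel_csv(rec$channels[[ch]], file.path(d, paste0(ch, ".csv")))
    write_ibi_csv(rec$ibi, file.path(d, "IBI.csv"))
  }
  write_market_csv(unlist(cohort$markets, recursive = FALSE),
                   file.path(dir, "markets.csv"))
  write_transactions_csv(cohort$transactions, file.path(dir, "transactions.csv"))
  write_profiles_csv(cohort$profiles, file.path(dir, "profiles.csv"))
  write_results(cohort$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
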