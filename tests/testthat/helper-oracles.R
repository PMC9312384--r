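# Independent oracles and small constructors shared across the test files.

# textbook step-down Holm-Bonferroni, written directly from the definition:
# sort ascending, reject while p_(k) <= alpha / (m - k + 1), stop at the
# first failure, map back to input order
holm_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  if (!m) return(logical())
  o <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[o[k]] <= alpha / (m - k + 1)) reject[o[k]] <- TRUE else break
  }
  reject
}

# brute-force expanding-moment squared Mahalanobis: recompute mean and sample
# covariance from scratch at every t, straight from the definition
mahal_brute <- function(Y, valid, min_history, ridge_frac) {
  n <- nrow(Y); d <- ncol(Y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    idx <- which(valid[seq_len(i)])
    if (length(idx) < min_history) next
    Z <- Y[idx, , drop = FALSE]
    mu <- colMeans(Z)
    S <- cov(Z)
    md <- mean(diag(S))
    eps <- ridge_frac * (if (md > 0) md else 1)
    dev <- Y[i, ] - mu
    out[i] <- max(sum(dev * solve(S + eps * diag(d), dev)), 0)
  }
  out
}

# minimal activation-series object for tests that construct z/dM directly
make_act <- function(timestamps, dM, trader_id = "T01",
                     day = as.Date("2020-03-02"), valid = NULL) {
  valid <- valid %||% rep(TRUE, length(dM))
  mu <- mean(dM[valid]); sigma <- sd(dM[valid])
  z <- rep(NA_real_, length(dM))
  if (isTRUE(sigma > 0)) z[valid] <- (dM[valid] - mu) / sigma
  structure(list(trader_id = trader_id, day = day, timestamps = timestamps,
                 dM = dM, valid = valid, day_mean = mu, day_sd = sigma,
                 z = z, mode = "overall"),
            class = "activation_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trader-day panel with a known linear attribution model planted directly
plant_dataset <- function(n = 250, beta = NULL, sigma = 0, seed = 31) {
  set.seed(seed)
  beta <- beta %||% list(intercept = 9, division = c(eq = 0, fi = 0.3,
                                                     fx = -0.2),
                         gender_male = -0.02, amt = 0.02,
                         experience = -0.02, numT = 4e-5, vol = 0.15)
  ids <- sprintf("T%02d", seq_len(n %/% 5 + 1))
  df <- data.frame(
    trader_id = rep(ids, length.out = n),
    day = rep(as.Date("2020-03-02") + 0:4, each = ceiling(n / 5))[1:n])
  prof <- data.frame(trader_id = ids,
                     gender = sample(c("female", "male"), length(ids), TRUE),
                     experience_years = runif(length(ids), 1, 25),
                     division = sample(names(beta$division), length(ids), TRUE))
  df <- merge(df, prof)
  df$amt <- rlnorm(n, 0, 1)
  df$numT <- rpois(n, 8)
  df$vol_IG <- runif(n, 0.5, 2)
  df$y <- beta$intercept +
    beta$division[df$division] +
    beta$gender_male * (df$gender == "male") +
    beta$amt * df$amt + beta$experience * df$experience_years +
    beta$numT * df$numT + beta$vol * df$vol_IG +
    rnorm(n, sd = sigma)
  class(df) <- c("attribution_dataset", "data.frame")
  list(ds = df, beta = beta)
}

# constant-rate channel filled with a function of time-offset seconds
make_channel <- function(name, rate, dur_s, f, start = 1585000000) {
  ts <- (seq_len(dur_s * rate) - 1) / rate
  ppactiv::channel_series(name, start, rate, f(ts))
}

# uniform RR stream covering dur_s seconds
make_ibi <- function(rr, start = 1585000000) {
  ppactiv::ibi_series(start, cumsum(rr), rr)
}

# small physio recording with controllable channels (defaults are benign)
make_recording <- function(dur_s = 900, start = 1585000000,
                           rr = NULL, eda_f = NULL, bvp_f = NULL,
                           temp_f = NULL) {
  rr <- rr %||% rep(0.8, ceiling(dur_s / 0.8) + 2)
  rr <- rr[cumsum(rr) <= dur_s]
  ibi <- make_ibi(rr, start)
  eda_f <- eda_f %||% function(ts) 0.5 + 0.01 * sin(ts / 60)
  bvp_f <- bvp_f %||% function(ts) sin(2 * pi * 1.25 * ts)
  temp_f <- temp_f %||% function(ts) 33 + 1e-4 * ts
  ppactiv::physio_recording(
    "T01", as.Date("2020-03-02"),
    channels = list(
      EDA = make_channel("EDA", 4, dur_s, eda_f, start),
      BVP = make_channel("BVP", 64, dur_s, bvp_f, start),
      TEMP = make_channel("TEMP", 4, dur_s, temp_f, start),
      HR = make_channel("HR", 1, dur_s, function(ts) 75 + 0 * ts, start)),
    ibi = ibi, session_span = c(start, start + dur_s))
}
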