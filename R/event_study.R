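# Transaction-centered event study of z-scored activation.
#
# For a transaction at time l, the z-scored activation is averaged in twelve
# half-open 5-minute windows partitioning [l - 30 min, l + 30 min); profiles
# are averaged first within a trader-day (over its transactions), then across
# trader-days, with a normal-approximation 95% confidence band across
# trader-day profiles.

event_offsets <- seq(-30, 25, by = 5)  # window starts, minutes

#' Windowed activation profile around one transaction
#'
#' Mean of the valid z-scored activation samples in each of the twelve
#' half-open 5-minute windows `[l - 30, l - 25), ..., [l + 25, l + 30)`
#' minutes around the transaction time `l`. Windows without a valid sample
#' are `NA`.
#'
#' @param act an `activation_series` (with z-scores).
#' @param l transaction time, epoch seconds; must lie so that the full
#'   +/- 30 minute frame is inside the recording span.
#' @return numeric vector of 12 window means, named by window start offset in
#'   minutes.
#' @export
transaction_profile <- function(act, l) {
  stopifnot(inherits(act, "activation_series"))
  span <- range(act$timestamps)
  if (l - 1800 < span[1] - 1 || l + 1800 > span[2] + 1)
    stop_ppactiv("transaction at ", l, " outside the +/-30 min coverage of ",
                 "the recording", class = "ppactiv_skip")
  out <- setNames(rep(NA_real_, 12), sprintf("%+d", event_offsets))
  ok <- act$valid & !is.na(act$z)
  ts <- act$timestamps
  n <- length(ts)
  contiguous <- n > 1 && ts[n] - ts[1] == n - 1
  if (contiguous) {
    # 1 Hz integer grid: windows become index ranges, means via prefix sums
    z0 <- ifelse(ok, act$z, 0)
    Sz <- cumsum(z0); Sn <- cumsum(as.numeric(ok))
    pick <- function(a, b) {  # sum over ts in [a, b)
      i <- max(ceiling(a - ts[1]) + 1, 1)
      j <- min(floor(b - 1e-9 - ts[1]) + 1, n)
      if (j < i) return(c(0, 0))
      c(Sz[j] - if (i > 1) Sz[i - 1] else 0,
        Sn[j] - if (i > 1) Sn[i - 1] else 0)
    }
    for (k in seq_along(event_offsets)) {
      a <- l + event_offsets[k] * 60
      p <- pick(a, a + 300)
      if (p[2] > 0) out[k] <- p[1] / p[2]
    }
  } else {
    rel <- ts - l
    for (k in seq_along(event_offsets)) {
      a <- event_offsets[k] * 60
      sel <- ok & rel >= a & rel < a + 300
      if (any(sel)) out[k] <- mean(act$z[sel])
    }
  }
  out
}

#' Aggregate event-study profile across transactions, traders and days
#'
#' Two-level unweighted averaging: transaction profiles are first averaged
#' within each trader-day, then across trader-days. The 95% confidence band
#' is `mean +/- 1.96 * sd / sqrt(n)` per window across the trader-day
#' profiles (`band = "normal"`), or a seeded bootstrap over trader-days
#' (`band = "bootstrap"`).
#'
#' @param acts list of `activation_series`.
#' @param log a [transaction_log()].
#' @param band `"normal"` or `"bootstrap"`.
#' @param boot_reps bootstrap resamples (default 1000).
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class `event_study_profile`: `offset_min` (window start
#'   offsets), `mean_z`, `lower`, `upper`, `n_trader_days`, `n_transactions`,
#'   `skipped`.
#' @export
aggregate_event_study <- function(acts, log, band = c("normal", "bootstrap"),
                                  boot_reps = 1000, boot_seed = 1) {
  band <- match.arg(band)
  stopifnot(length(acts) >= 1)
  tx <- as.data.frame(log)
  profiles <- list()
  n_tx <- 0; n_skipped <- 0
  for (act in acts) {
    span <- range(act$timestamps)
    day_tx <- tx$timestamp[tx$trader_id == act$trader_id &
                             tx$timestamp >= span[1] & tx$timestamp <= span[2]]
    if (!length(day_tx)) next
    mats <- list()
    for (l in day_tx) {
      p <- tryCatch(transaction_profile(act, l),
                    ppactiv_skip = function(e) NULL)
      if (is.null(p)) { n_skipped <- n_skipped + 1; next }
      mats[[length(mats) + 1]] <- p
    }
    if (!length(mats)) next
    n_tx <- n_tx + length(mats)
    profiles[[length(profiles) + 1]] <- colMeans(do.call(rbind, mats), na.rm = TRUE)
  }
  if (!length(profiles))
    stop_ppactiv("no usable transactions for the event study",
                 class = "ppactiv_empty")
  P <- do.call(rbind, profiles)
  mu <- colMeans(P, na.rm = TRUE)
  n <- nrow(P)
  if (band == "normal") {
    se <- apply(P, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
    })
    lower <- mu - 1.96 * se
    upper <- mu + 1.96 * se
  } else {
    set.seed(boot_seed)
    bm <- replicate(boot_reps,
                    colMeans(P[sample.int(n, n, replace = TRUE), , drop = FALSE],
                             na.rm = TRUE))
    lower <- apply(bm, 1, stats::quantile, 0.025, na.rm = TRUE)
    upper <- apply(bm, 1, stats::quantile, 0.975, na.rm = TRUE)
  }
  structure(list(offset_min = event_offsets, mean_z = unname(mu),
                 lower = unname(lower), upper = unname(upper),
                 n_trader_days = n, n_transactions = n_tx,
                 skipped = n_skipped, band = band),
            class = "event_study_profile")
}

#' @export
print.event_study_profile <- function(x, ...) {
  cat(sprintf("<event_study_profile> %d trader-days, %d transactions (%d skipped)\n",
              x$n_trader_days, x$n_transactions, x$skipped))
  df <- data.frame(window = sprintf("[%+d,%+d)", x$offset_min, x$offset_min + 5),
                   mean_z = round(x$mean_z, 4),
                   lower = round(x$lower, 4), upper = round(x$upper, 4))
  print(df, row.names = FALSE)
  invisible(x)
}
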