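# Physiological feature extraction on a 1 Hz grid.
#
# Eleven features in fixed column order: four time-domain HRV statistics from
# the inter-beat stream (mHR, mRRi, SDNN, RMSSD), three electrodermal features
# (mAmp, Slope, Events), three blood-volume-pulse summaries (mean absolute
# value, min, max) and the skin-temperature slope. All windows are trailing
# (t - window, t]: a feature at time t never sees a sample after t.

#' Names of the eleven activation features, in canonical column order
#' @export
ppactiv_features <- c("mHR", "mRRi", "SDNN", "RMSSD",
                      "mAmp", "Slope", "Events",
                      "BVPmeanAbs", "BVPmin", "BVPmax", "TEMPslope")

#' Feature columns belonging to each physiological family
#' @export
ppactiv_families <- list(
  hrv = c("mHR", "mRRi", "SDNN", "RMSSD"),
  eda = c("mAmp", "Slope", "Events"),
  bvp = c("BVPmeanAbs", "BVPmin", "BVPmax"),
  temp = "TEMPslope")

#' Time-domain HRV features over a trailing window
#'
#' From the beats in `(t - window_s, t]`: `mHR` = 60 / mean RR (beats/min),
#' `mRRi` = mean RR (ms), `SDNN` = sample standard deviation of RR (ms), and
#' `RMSSD` = root mean square of successive RR differences (ms) over
#' consecutive beat pairs that both fall inside the window. With fewer than
#' two beats all four are `NA`; with exactly two, `RMSSD` alone is `NA`.
#'
#' @param ibi an [ibi_series()].
#' @param t evaluation time, epoch seconds.
#' @param window_s trailing window length in seconds (default 300, i.e. the
#'   5-minute window the features are defined over).
#' @return named numeric vector `(mHR, mRRi, SDNN, RMSSD)`.
#' @export
hrv_features <- function(ibi, t, window_s = 300) {
  stopifnot(inherits(ibi, "ibi_series"), window_s > 0)
  bt <- ibi$start_time + ibi$offsets
  sel <- bt > t - window_s & bt <= t
  rr <- ibi$rr[sel]
  out <- c(mHR = NA_real_, mRRi = NA_real_, SDNN = NA_real_, RMSSD = NA_real_)
  n <- length(rr)
  if (n < 2) return(out)
  out["mHR"] <- 60 / mean(rr)
  out["mRRi"] <- mean(rr) * 1000
  out["SDNN"] <- sd(rr) * 1000
  if (n >= 3) out["RMSSD"] <- sqrt(mean(diff(rr)^2)) * 1000
  out
}

#' Detect skin-conductance responses in an EDA channel
#'
#' A skin-conductance response (SCR) is a rapid phasic rise in skin
#' conductance. The detector finds maximal strictly-rising runs of the signal
#' and counts a run as one event if some sub-segment shorter than
#' `max_rise_s` seconds rises by more than `min_rise_uS` microsiemens;
#' qualifying detections inside one rising run merge into a single event, so a
#' long continuous rise is never counted twice.
#'
#' @param eda an EDA [channel_series()] (microsiemens).
#' @param span optional `(start, end)` epoch seconds restricting the search;
#'   must lie within the channel.
#' @param min_rise_uS rise threshold, default 0.05 uS.
#' @param max_rise_s rise-time bound, default 5 s (the rise must complete in
#'   strictly less than this).
#' @return data.frame with columns `onset_s`, `peak_s` (epoch seconds) and
#'   `amplitude_uS` (total rise of the run), one row per event.
#' @export
detect_scr_events <- function(eda, span = NULL, min_rise_uS = 0.05,
                              max_rise_s = 5) {
  stopifnot(inherits(eda, "channel_series"))
  ts <- channel_times(eda)
  v <- eda$values
  if (!is.null(span)) {
    if (span[1] < eda$start_time - 1e-9 || span[2] > ts[length(ts)] + 1e-9)
      stop_ppactiv("span outside EDA channel range", class = "ppactiv_range")
    keep <- ts >= span[1] & ts <= span[2]
    ts <- ts[keep]; v <- v[keep]
  }
  empty <- data.frame(onset_s = numeric(), peak_s = numeric(),
                      amplitude_uS = numeric())
  n <- length(v)
  if (n < 2) return(empty)
  d <- diff(v)
  up <- !is.na(d) & d > 0
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ri <- which(r$values)
  if (!length(ri)) return(empty)
  rs <- starts[ri]           # first pair index -> run start sample
  re <- ends[ri] + 1L        # run end sample
  # earliest sample whose distance to s is < max_rise_s
  L <- ceiling(max_rise_s * eda$rate_hz)
  len <- re - rs + 1L
  s_idx <- sequence(len, from = rs)
  run_of <- rep(seq_along(ri), len)
  a_idx <- pmax(rep(rs, len), s_idx - L + 1L)
  qual <- (v[s_idx] - v[a_idx] > min_rise_uS) &
    (ts[s_idx] - ts[a_idx] < max_rise_s)
  hit <- rowsum(as.numeric(qual), run_of) > 0
  keep <- which(hit)
  data.frame(onset_s = ts[rs[keep]], peak_s = ts[re[keep]],
             amplitude_uS = v[re[keep]] - v[rs[keep]])
}

#' Electrodermal features over a trailing window
#'
#' `mAmp` = mean of the raw skin-conductance samples in `(t - window_s, t]`
#' (uS); `Slope` = mean absolute first difference of in-window sample pairs,
#' reported per second (uS/s, i.e. multiplied by the sampling rate so it is
#' rate-invariant); `Events` = number of SCR peaks (see
#' [detect_scr_events()]) in the window.
#'
#' @inheritParams hrv_features
#' @param eda an EDA [channel_series()].
#' @param events optional precomputed [detect_scr_events()] table for the
#'   whole channel (avoids re-detection when evaluating many `t`).
#' @return named numeric vector `(mAmp, Slope, Events)`.
#' @export
eda_features <- function(eda, t, window_s = 300, events = NULL) {
  stopifnot(inherits(eda, "channel_series"))
  ts <- channel_times(eda)
  sel <- ts > t - window_s & ts <= t
  x <- eda$values[sel]
  out <- c(mAmp = NA_real_, Slope = NA_real_, Events = NA_real_)
  if (sum(!is.na(x)) < 2) return(out)
  out["mAmp"] <- mean(x, na.rm = TRUE)
  d <- abs(diff(x))                      # adjacent sample pairs only
  d <- d[!is.na(d)]
  if (length(d)) out["Slope"] <- mean(d) * eda$rate_hz
  if (is.null(events)) events <- detect_scr_events(eda)
  out["Events"] <- sum(events$peak_s > t - window_s & events$peak_s <= t)
  out
}

#' Blood-volume-pulse features over a trailing window
#'
#' Mean absolute value, minimum and maximum of the BVP samples in
#' `(t - window_s, t]`.
#'
#' @inheritParams hrv_features
#' @param bvp a BVP [channel_series()].
#' @return named numeric vector `(BVPmeanAbs, BVPmin, BVPmax)`.
#' @export
bvp_features <- function(bvp, t, window_s = 300) {
  stopifnot(inherits(bvp, "channel_series"))
  ts <- channel_times(bvp)
  x <- bvp$values[ts > t - window_s & ts <= t]
  x <- x[!is.na(x)]
  if (!length(x))
    return(c(BVPmeanAbs = NA_real_, BVPmin = NA_real_, BVPmax = NA_real_))
  c(BVPmeanAbs = mean(abs(x)), BVPmin = min(x), BVPmax = max(x))
}

#' Skin-temperature rate of change
#'
#' Least-squares slope (degrees Celsius per second) of the TEMP samples in
#' the trailing window `(t - slope_window_s, t]`, the operationalization of
#' the instantaneous rate of change of skin temperature.
#'
#' @inheritParams hrv_features
#' @param temp a TEMP [channel_series()].
#' @param slope_window_s trailing window, default 60 s.
#' @return `TEMPslope` (degC/s), `NA` with fewer than two samples.
#' @export
temp_slope <- function(temp, t, slope_window_s = 60) {
  stopifnot(inherits(temp, "channel_series"))
  ts <- channel_times(temp)
  sel <- ts > t - slope_window_s & ts <= t
  x <- temp$values[sel]; tt <- ts[sel]
  ok <- !is.na(x)
  x <- x[ok]; tt <- tt[ok]
  if (length(x) < 2) return(c(TEMPslope = NA_real_))
  tc <- tt - mean(tt)
  c(TEMPslope = sum(tc * (x - mean(x))) / sum(tc^2))
}

# ---- vectorized whole-day evaluation -------------------------------------

# NA-aware trailing-window sums over a uniform channel, evaluated at the grid
# times: returns list(sum, sumabs, n) for samples in (t - window, t]
window_index <- function(chan, tgrid, window_s) {
  m <- length(chan$values)
  i2 <- pmin(pmax(floor((tgrid - chan$start_time) * chan$rate_hz + 1e-9) + 1, 0), m)
  i1 <- pmin(pmax(floor((tgrid - window_s - chan$start_time) * chan$rate_hz + 1e-9) + 1, 0), m)
  list(i1 = i1, i2 = i2)
}

cum_pick <- function(cs, i1, i2) cs[i2 + 1] - cs[i1 + 1]

hrv_features_grid <- function(ibi, tgrid, window_s) {
  bt <- ibi$start_time + ibi$offsets
  rr <- ibi$rr
  N <- length(rr)
  out <- matrix(NA_real_, length(tgrid), 4,
                dimnames = list(NULL, ppactiv_families$hrv))
  if (N < 2) return(out)
  i2 <- findInterval(tgrid, bt)
  i1 <- findInterval(tgrid - window_s, bt)
  n <- i2 - i1
  S1 <- cumsum(c(0, rr))
  rrc <- rr - mean(rr)                   # centering avoids cancellation
  S1c <- cumsum(c(0, rrc)); S2c <- cumsum(c(0, rrc^2))
  srr <- cum_pick(S1, i1, i2)
  src <- cum_pick(S1c, i1, i2); src2 <- cum_pick(S2c, i1, i2)
  ok <- n >= 2
  mu <- srr / n
  out[ok, "mHR"] <- 60 / mu[ok]
  out[ok, "mRRi"] <- mu[ok] * 1000
  vv <- pmax((src2 - src^2 / n) / (n - 1), 0)
  out[ok, "SDNN"] <- sqrt(vv[ok]) * 1000
  d2 <- c(0, diff(rr)^2)                 # d2[j]: pair (j-1, j)
  C2 <- cumsum(c(0, d2))
  np <- i2 - i1 - 1
  sp <- C2[i2 + 1] - C2[pmin(i1 + 1, i2) + 1]   # pairs j in (i1+1, i2]
  ok3 <- n >= 3
  out[ok3, "RMSSD"] <- sqrt(sp[ok3] / np[ok3]) * 1000
  out
}

eda_features_grid <- function(eda, tgrid, window_s) {
  out <- matrix(NA_real_, length(tgrid), 3,
                dimnames = list(NULL, ppactiv_families$eda))
  v <- eda$values
  idx <- window_index(eda, tgrid, window_s)
  fin <- !is.na(v)
  v0 <- v; v0[!fin] <- 0
  Sv <- cumsum(c(0, v0))
  Sn <- cumsum(c(0, as.numeric(fin)))
  n <- cum_pick(Sn, idx$i1, idx$i2)
  ok <- n >= 2
  out[ok, "mAmp"] <- (cum_pick(Sv, idx$i1, idx$i2) / n)[ok]
  ad <- c(0, abs(diff(v)))               # ad[j]: pair (j-1, j)
  padok <- !is.na(ad); padok[1] <- FALSE
  ad[!padok] <- 0
  Sd <- cumsum(c(0, ad))
  Sdn <- cumsum(c(0, as.numeric(padok)))
  npair <- Sdn[idx$i2 + 1] - Sdn[pmin(idx$i1 + 1, idx$i2) + 1]
  sdiff <- Sd[idx$i2 + 1] - Sd[pmin(idx$i1 + 1, idx$i2) + 1]
  okp <- ok & npair >= 1
  out[okp, "Slope"] <- (sdiff / npair)[okp] * eda$rate_hz
  ev <- detect_scr_events(eda)
  cnt <- findInterval(tgrid, ev$peak_s) - findInterval(tgrid - window_s, ev$peak_s)
  out[ok, "Events"] <- cnt[ok]
  out
}

bvp_features_grid <- function(bvp, tgrid, window_s) {
  out <- matrix(NA_real_, length(tgrid), 3,
                dimnames = list(NULL, ppactiv_families$bvp))
  v <- bvp$values
  idx <- window_index(bvp, tgrid, window_s)
  fin <- !is.na(v)
  va <- abs(v); va[!fin] <- 0
  Sa <- cumsum(c(0, va))
  Sn <- cumsum(c(0, as.numeric(fin)))
  n <- cum_pick(Sn, idx$i1, idx$i2)
  ok <- n >= 1
  out[ok, "BVPmeanAbs"] <- (cum_pick(Sa, idx$i1, idx$i2) / n)[ok]
  w <- idx$i2 - idx$i1
  wfull <- as.integer(round(window_s * bvp$rate_hz))
  full <- ok & w == wfull & idx$i2 >= wfull
  if (any(full)) {
    block <- as.integer(round(bvp$rate_hz))
    blocked <- block >= 1 && abs(bvp$rate_hz - block) < 1e-9 &&
      wfull %% block == 0 && all((idx$i2[full] - 1) %% block == 0)
    if (blocked) {
      # windows end one sample past a block boundary (the sample at exactly
      # t is included), so block the one-shifted array: window (i1, i2] of v
      # is then a whole number of blocks of u = v[-1]
      u <- v[-1]
      wb <- wfull %/% block
      rmin <- rolling_extreme(block_extreme(u, block, "min"), wb, "min")
      rmax <- rolling_extreme(block_extreme(u, block, "max"), wb, "max")
      out[full, "BVPmin"] <- rmin[(idx$i2[full] - 1) %/% block]
      out[full, "BVPmax"] <- rmax[(idx$i2[full] - 1) %/% block]
    } else {
      rmin <- rolling_extreme(v, wfull, "min")
      rmax <- rolling_extreme(v, wfull, "max")
      out[full, "BVPmin"] <- rmin[idx$i2[full]]
      out[full, "BVPmax"] <- rmax[idx$i2[full]]
    }
  }
  # partial windows (warm-up / trailing edge): direct evaluation
  part <- which(ok & !full)
  for (k in part) {
    xx <- v[(idx$i1[k] + 1):idx$i2[k]]
    xx <- xx[!is.na(xx)]
    out[k, "BVPmin"] <- min(xx); out[k, "BVPmax"] <- max(xx)
  }
  out
}

temp_slope_grid <- function(temp, tgrid, window_s) {
  out <- matrix(NA_real_, length(tgrid), 1, dimnames = list(NULL, "TEMPslope"))
  v <- temp$values
  idx <- window_index(temp, tgrid, window_s)
  nraw <- idx$i2 - idx$i1
  hasna <- cumsum(c(0, as.numeric(is.na(v))))
  nas <- cum_pick(hasna, idx$i1, idx$i2)
  ok <- nraw >= 2 & nas == 0
  if (!any(ok)) return(out)
  j <- seq_along(v)
  Sx <- cumsum(c(0, ifelse(is.na(v), 0, v)))
  Sjx <- cumsum(c(0, ifelse(is.na(v), 0, j * v)))
  n <- nraw
  jbar <- (idx$i1 + 1 + idx$i2) / 2
  num <- cum_pick(Sjx, idx$i1, idx$i2) - jbar * cum_pick(Sx, idx$i1, idx$i2)
  den <- n * (n^2 - 1) / 12
  out[ok, "TEMPslope"] <- (num / den)[ok] * temp$rate_hz
  # rows with missing samples fall back to the exact per-point computation
  bad <- which(nraw >= 2 & nas > 0)
  for (k in bad) out[k, "TEMPslope"] <- temp_slope(temp, tgrid[k], window_s)
  out
}

#' Assemble the 1 Hz feature series for one trader-day
#'
#' Evaluates all eleven features at every whole second of the recording's
#' session span, with trailing windows. A row is valid only when the full
#' feature window has elapsed since session start and every feature is
#' computable; no value is ever imputed.
#'
#' @param rec a [physio_recording()] with channels `EDA`, `TEMP`, `BVP` and a
#'   non-empty inter-beat series.
#' @param config list of window lengths: `window_s` (HRV/EDA/BVP trailing
#'   window, default 300) and `temp_slope_window_s` (default 60).
#' @return an object of class `feature_series`: `timestamps` (1 Hz epoch
#'   seconds), `matrix` (rows x 11 named features), `valid` mask, and the
#'   trader-day identity.
#' @export
assemble_feature_series <- function(rec, config = list()) {
  stopifnot(inherits(rec, "physio_recording"))
  window_s <- config$window_s %||% 300
  tw <- config$temp_slope_window_s %||% 60
  for (ch in c("EDA", "TEMP", "BVP")) {
    if (is.null(rec$channels[[ch]]))
      stop_ppactiv("required channel missing from recording: ", ch,
                   class = "ppactiv_config")
  }
  if (!length(rec$ibi$offsets))
    stop_ppactiv("required channel missing from recording: IBI",
                 class = "ppactiv_config")
  s0 <- floor(rec$session_span[1])
  tgrid <- seq(s0 + 1, floor(rec$session_span[2]))
  mat <- cbind(
    hrv_features_grid(rec$ibi, tgrid, window_s),
    eda_features_grid(rec$channels$EDA, tgrid, window_s),
    bvp_features_grid(rec$channels$BVP, tgrid, window_s),
    temp_slope_grid(rec$channels$TEMP, tgrid, tw))
  mat <- mat[, ppactiv_features, drop = FALSE]
  valid <- (tgrid - s0 >= window_s) & rowSums(is.na(mat)) == 0
  structure(list(trader_id = rec$trader_id, day = rec$day,
                 timestamps = tgrid, matrix = mat, valid = valid),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> trader %s, %s: %d rows (%d valid) x %d features\n",
              x$trader_id, format(x$day), length(x$timestamps), sum(x$valid),
              ncol(x$matrix)))
  invisible(x)
}

#' Export a feature series as CSV
#' @param fs a `feature_series`.
#' @param path destination file.
#' @export
write_features_csv <- function(fs, path) {
  df <- data.frame(timestamp = fs$timestamps, fs$matrix, valid = fs$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
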