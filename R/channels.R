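#' Uniform-rate physiological channel
#'
#' A single wearable channel sampled at a constant rate: sample `k` (1-based)
#' is taken at `start_time + (k - 1) / rate_hz` (epoch seconds, UTC). Units
#' follow the device convention: microsiemens for EDA, degrees Celsius for
#' TEMP, beats/min for HR, device units for BVP and the accelerometer axes.
#' Missing samples are encoded as `NA`.
#'
#' @param name channel label, e.g. `"BVP"`, `"EDA"`, `"TEMP"`, `"HR"`,
#'   `"ACC_X"`, `"ACC_Y"`, `"ACC_Z"`.
#' @param start_time epoch seconds (UTC) of the first sample.
#' @param rate_hz sampling rate in samples/second, `> 0`.
#' @param values numeric vector of samples (`NA` = missing).
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(name, start_time, rate_hz, values) {
  if (!is_scalar_number(rate_hz) || rate_hz <= 0)
    stop_ppactiv("rate_hz must be a positive number", class = "ppactiv_validation")
  if (!is_scalar_number(start_time))
    stop_ppactiv("start_time must be a finite epoch-seconds scalar",
                 class = "ppactiv_validation")
  structure(
    list(name = as.character(name), start_time = as.numeric(start_time),
         rate_hz = as.numeric(rate_hz), values = as.numeric(values)),
    class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %s: %d samples @ %g Hz from t=%.0f\n",
              x$name, length(x$values), x$rate_hz, x$start_time))
  invisible(x)
}

#' Sample timestamps of a channel
#' @param x a [channel_series()].
#' @return epoch seconds of each sample.
#' @export
channel_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1) / x$rate_hz
}

#' Irregular inter-beat-interval series
#'
#' Beat events from the pulse sensor: each event is the arrival time of a
#' heartbeat (`offset_s` seconds after `start_time`) together with the length
#' of the preceding inter-beat (RR) interval in seconds. Offsets must be
#' strictly increasing and every RR interval positive and no longer than the
#' gap to the previous event (a larger gap means beats were dropped by the
#' device).
#'
#' @param start_time epoch seconds (UTC).
#' @param offsets seconds since `start_time` of each beat, strictly increasing.
#' @param rr preceding inter-beat interval of each beat, seconds, `> 0`.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(start_time, offsets, rr) {
  offsets <- as.numeric(offsets); rr <- as.numeric(rr)
  if (length(offsets) != length(rr))
    stop_ppactiv("offsets and rr must have equal length", class = "ppactiv_validation")
  if (length(offsets) > 1 && any(diff(offsets) <= 0))
    stop_ppactiv("non-increasing offsets in IBI series", class = "ppactiv_validation")
  if (any(rr <= 0))
    stop_ppactiv("non-positive RR interval in IBI series", class = "ppactiv_validation")
  structure(list(start_time = as.numeric(start_time), offsets = offsets, rr = rr),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d beats from t=%.0f\n",
              length(x$offsets), x$start_time))
  invisible(x)
}

#' One trader-day of wearable recordings
#'
#' Bundles the uniform-rate channels and the irregular inter-beat series for
#' one trader on one trading day, together with the session span the analysis
#' grid is laid over.
#'
#' @param trader_id trader identifier.
#' @param day the trading day (`Date` or coercible).
#' @param channels named list of [channel_series()].
#' @param ibi an [ibi_series()].
#' @param session_span numeric length-2 `(start, end)` epoch seconds.
#' @return an object of class `physio_recording`.
#' @export
physio_recording <- function(trader_id, day, channels, ibi, session_span) {
  if (length(session_span) != 2 || session_span[2] <= session_span[1])
    stop_ppactiv("session_span must be (start, end) with end > start",
                 class = "ppactiv_validation")
  if (!all(vapply(channels, inherits, logical(1), "channel_series")))
    stop_ppactiv("channels must all be channel_series objects",
                 class = "ppactiv_validation")
  structure(
    list(trader_id = as.character(trader_id), day = as.Date(day),
         channels = channels, ibi = ibi,
         session_span = as.numeric(session_span)),
    class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> trader %s, %s: channels [%s], %d beats, span %.0f s\n",
              x$trader_id, format(x$day), paste(names(x$channels), collapse = ", "),
              length(x$ibi$offsets), diff(x$session_span)))
  invisible(x)
}

#' Minute-level market-index series
#'
#' @param index_name index label (e.g. `"CDS_IG"`).
#' @param timestamps epoch seconds, strictly increasing, 60 s spacing within a
#'   trading day.
#' @param values index levels/prices.
#' @return an object of class `market_series`.
#' @export
market_series <- function(index_name, timestamps, values) {
  timestamps <- as.numeric(timestamps); values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop_ppactiv("timestamps and values must have equal length",
                 class = "ppactiv_validation")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop_ppactiv("market timestamps must be strictly increasing",
                 class = "ppactiv_validation")
  structure(list(index_name = as.character(index_name),
                 timestamps = timestamps, values = values),
            class = "market_series")
}

#' @export
print.market_series <- function(x, ...) {
  cat(sprintf("<market_series> %s: %d minutes\n", x$index_name, length(x$values)))
  invisible(x)
}

#' Transaction log
#'
#' @param trader_id character vector of trader identifiers.
#' @param timestamp epoch seconds of each transaction.
#' @param amount_usd positive dollar amounts.
#' @return a `data.frame` of class `transaction_log`.
#' @export
transaction_log <- function(trader_id = character(), timestamp = numeric(),
                            amount_usd = numeric()) {
  if (any(amount_usd <= 0))
    stop_ppactiv("transaction amounts must be positive",
                 class = "ppactiv_validation")
  df <- data.frame(trader_id = as.character(trader_id),
                   timestamp = as.numeric(timestamp),
                   amount_usd = as.numeric(amount_usd),
                   stringsAsFactors = FALSE)
  class(df) <- c("transaction_log", "data.frame")
  df
}

#' Trader covariate table
#'
#' @param trader_id trader identifiers (unique).
#' @param gender categorical gender labels.
#' @param experience_years trading experience in years, `>= 0`.
#' @param division business-division labels.
#' @return a `data.frame` of class `trader_profiles`.
#' @export
trader_profiles <- function(trader_id, gender, experience_years, division) {
  if (any(experience_years < 0))
    stop_ppactiv("experience_years must be >= 0", class = "ppactiv_validation")
  if (anyDuplicated(trader_id))
    stop_ppactiv("duplicate trader_id in profiles", class = "ppactiv_validation")
  df <- data.frame(trader_id = as.character(trader_id),
                   gender = as.character(gender),
                   experience_years = as.numeric(experience_years),
                   division = as.character(division),
                   stringsAsFactors = FALSE)
  class(df) <- c("trader_profiles", "data.frame")
  df
}
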