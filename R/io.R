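# On-disk formats.
#
# Channel files follow the wristband-style export dialect: line 1 = epoch
# start time, line 2 = sampling rate (Hz), lines 3+ = one sample per line
# (NA/NaN marks a missing sample). IBI files: line 1 = epoch start time,
# lines 2+ = "offset_s,rr_s". Market/transaction/profile tables are headered
# CSV. Analysis results are JSON with a type tag, package version and config
# hash, written at full double precision.

parse_num_line <- function(line, lineno, what, path) {
  v <- suppressWarnings(as.numeric(line))
  if (is.na(v) && !(trimws(line) %in% c("NA", "NaN", "nan")))
    stop_ppactiv(sprintf("%s: line %d: expected %s, got '%s'",
                         path, lineno, what, line),
                 class = "ppactiv_format")
  v
}

#' Read a device-export channel CSV
#'
#' Dialect: line 1 is the epoch start time, line 2 the sampling rate in Hz,
#' and each following line one sample. `NA`/`NaN` lines are kept as missing
#' samples. The channel name is taken from the file name stem unless given.
#'
#' @param path file path.
#' @param name channel label; default is the file name without extension.
#' @return a [channel_series()].
#' @export
read_channel_csv <- function(path, name = NULL) {
  if (!file.exists(path))
    stop_ppactiv("no such file: ", path, class = "ppactiv_io")
  lines <- readLines(path)
  if (length(lines) < 2)
    stop_ppactiv(path, ": malformed header: need start-time and rate lines",
                 class = "ppactiv_format")
  start <- parse_num_line(lines[1], 1, "epoch start time", path)
  rate <- parse_num_line(lines[2], 2, "sampling rate", path)
  if (is.na(start) || is.na(rate) || rate <= 0)
    stop_ppactiv(path, ": malformed header: line ",
                 if (is.na(start)) 1 else 2, class = "ppactiv_format")
  body <- lines[-(1:2)]
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals) & !(trimws(body) %in% c("NA", "NaN", "nan", "")))
  if (length(bad))
    stop_ppactiv(sprintf("%s: line %d: non-numeric sample '%s'",
                         path, bad[1] + 2, body[bad[1]]),
                 class = "ppactiv_format")
  vals <- vals[trimws(body) != ""]
  channel_series(name %||% sub("\\.[^.]*$", "", basename(path)),
                 start, rate, vals)
}

#' Write a channel to the device-export dialect
#' @param x a [channel_series()].
#' @param path destination file.
#' @export
write_channel_csv <- function(x, path) {
  stopifnot(inherits(x, "channel_series"))
  lines <- c(sprintf("%.10g", x$start_time), sprintf("%.10g", x$rate_hz),
             ifelse(is.na(x$values), "NaN", sprintf("%.10g", x$values)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an inter-beat-interval CSV
#'
#' Line 1 is the epoch start time; each following line is `offset_s,rr_s`.
#'
#' @param path file path.
#' @return an [ibi_series()].
#' @export
read_ibi_csv <- function(path) {
  if (!file.exists(path))
    stop_ppactiv("no such file: ", path, class = "ppactiv_io")
  lines <- readLines(path)
  if (length(lines) < 1)
    stop_ppactiv(path, ": empty IBI file", class = "ppactiv_format")
  start <- parse_num_line(lines[1], 1, "epoch start time", path)
  body <- lines[-1]
  body <- body[trimws(body) != ""]
  if (!length(body)) return(ibi_series(start, numeric(), numeric()))
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop_ppactiv(path, ": line ", which(lengths(parts) != 2)[1] + 1,
                 ": expected 'offset_s,rr_s'", class = "ppactiv_format")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m))
    stop_ppactiv(path, ": non-numeric IBI entry", class = "ppactiv_format")
  ibi_series(start, m[, 1], m[, 2])
}

#' @rdname read_ibi_csv
#' @param x an [ibi_series()].
#' @export
write_ibi_csv <- function(x, path) {
  stopifnot(inherits(x, "ibi_series"))
  lines <- c(sprintf("%.10g", x$start_time),
             sprintf("%.10g,%.10g", x$offsets, x$rr))
  writeLines(lines, path)
  invisible(path)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_ppactiv(path, ": missing required column(s): ",
                 paste(missing, collapse = ", "), class = "ppactiv_schema")
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s): %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  df[required]
}

#' Read minute-level market-index series
#'
#' Expects columns `index_name,timestamp,value`. Returns a named list of
#' [market_series()], one element per index present in the file (a length-1
#' list for a single-index file).
#'
#' @param path file path.
#' @return named list of [market_series()].
#' @export
read_market_csv <- function(path) {
  df <- check_columns(read.csv(path, stringsAsFactors = FALSE),
                      c("index_name", "timestamp", "value"), path)
  out <- lapply(split(df, df$index_name), function(d) {
    d <- d[order(d$timestamp), ]
    market_series(d$index_name[1], d$timestamp, d$value)
  })
  out[order(names(out))]
}

#' @rdname read_market_csv
#' @param markets a [market_series()] or list of them.
#' @export
write_market_csv <- function(markets, path) {
  if (inherits(markets, "market_series")) markets <- list(markets)
  df <- do.call(rbind, lapply(markets, function(m)
    data.frame(index_name = m$index_name, timestamp = m$timestamps,
               value = m$values)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transaction log CSV
#'
#' Expects columns `trader_id,timestamp,amount_usd`; non-positive amounts are
#' a validation error.
#'
#' @param path file path.
#' @return a [transaction_log()].
#' @export
read_transactions_csv <- function(path) {
  df <- check_columns(read.csv(path, stringsAsFactors = FALSE),
                      c("trader_id", "timestamp", "amount_usd"), path)
  transaction_log(df$trader_id, df$timestamp, df$amount_usd)
}

#' @rdname read_transactions_csv
#' @param x a [transaction_log()].
#' @export
write_transactions_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the trader covariate table
#'
#' Expects columns `trader_id,gender,experience_years,division`.
#'
#' @param path file path.
#' @return a [trader_profiles()].
#' @export
read_profiles_csv <- function(path) {
  df <- check_columns(read.csv(path, stringsAsFactors = FALSE),
                      c("trader_id", "gender", "experience_years", "division"),
                      path)
  trader_profiles(df$trader_id, df$gender, df$experience_years, df$division)
}

#' @rdname read_profiles_csv
#' @param x a [trader_profiles()].
#' @export
write_profiles_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis result to a typed JSON document
#'
#' Serializes any of the pipeline's result objects (activation summaries,
#' Granger scans, attribution fits, event-study profiles, ground truth, ...)
#' with a type tag, the package version, and a hash of the generating
#' configuration, at full double precision. [read_results()] restores the
#' object.
#'
#' @param obj the result object.
#' @param path destination file.
#' @param config optional configuration list; hashed into the document.
#' @export
write_results <- function(obj, path, config = NULL) {
  type <- class(obj)[1]
  doc <- list(
    type = type,
    pipeline_version = as.character(utils::packageVersion("ppactiv")),
    config_hash = config_hash(config),
    payload = serialize_result(obj))
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null",
                           na = "null")
  ok <- tryCatch({writeLines(json, path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ppactiv("cannot write results to ", path, class = "ppactiv_io")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  deserialize_result(doc$type, doc$payload)
}

# MD5 of the canonical JSON form of a configuration list
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, digits = NA, auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

serialize_result <- function(obj) {
  if (is.data.frame(obj)) return(as.data.frame(unclass(obj)))
  if (is.list(obj)) return(lapply(unclass(obj), serialize_result))
  obj
}

df_restore <- function(x, cls) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  class(df) <- c(cls, "data.frame")
  df
}

deserialize_result <- function(type, payload) {
  switch(type,
    activation_summary = ,
    activation_summaries = df_restore(payload, type),
    transaction_log = df_restore(payload, "transaction_log"),
    trader_profiles = df_restore(payload, "trader_profiles"),
    granger_scan = {
      out <- list(results = as.data.frame(payload$results),
                  per_index = as.data.frame(payload$per_index),
                  skipped = as.data.frame(payload$skipped),
                  alpha = payload$alpha, lag_order = payload$lag_order)
      class(out) <- "granger_scan"
      out
    },
    attribution_result = {
      out <- payload
      out$coefficients <- as.data.frame(payload$coefficients)
      class(out) <- "attribution_result"
      out
    },
    event_study_profile = {
      out <- payload
      class(out) <- "event_study_profile"
      out
    },
    ground_truth = {
      out <- payload
      for (nm in c("episodes", "coupling", "transactions", "uplift"))
        if (!is.null(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
      class(out) <- "ground_truth"
      out
    },
    histogram_set = {
      out <- payload
      out$stats <- as.data.frame(payload$stats)
      class(out) <- "histogram_set"
      out
    },
    payload)
}
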