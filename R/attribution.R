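# Attribution of average daily activation to trader covariates,
# transaction intensity, and market volatility:
#
#   y_{i,t} = alpha + beta * division_i + gamma * gender_i + delta * amt_{i,t}
#             + theta * experience_i + zeta * numT_{i,t} + eta' vol_t + e
#
# fitted by ordinary least squares on the trader-day panel.

#' Build the attribution regression dataset
#'
#' Joins trader-day activation summaries with trader covariates, per-day
#' transaction statistics (`amt` = mean dollar amount, `numT` = count;
#' zero-trade days keep `amt = 0` and the row is retained), and per-index
#' daily market volatilities (`vol_<index>` = standard deviation of the
#' minute-level first differences of that index on that day). Trader-days
#' without a covariate match are excluded with a logged reason.
#'
#' @param summaries row-bound [summarize_day()] data.frame.
#' @param profiles a [trader_profiles()].
#' @param transactions a [transaction_log()].
#' @param markets list of [market_series()] (possibly nested per day).
#' @param config list; `amt_scale` divides the dollar amounts (default `1e6`,
#'   i.e. `amt` in millions of dollars).
#' @return data.frame of class `attribution_dataset`; excluded rows in
#'   `attr(, "excluded")`.
#' @export
build_dataset <- function(summaries, profiles, transactions, markets,
                          config = list()) {
  amt_scale <- config$amt_scale %||% 1e6
  day_of <- function(ts) as.Date(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"))
  tx <- as.data.frame(transactions)
  tx$day <- if (nrow(tx)) as.character(day_of(tx$timestamp)) else character()
  ds <- merge(as.data.frame(summaries)[
    c("trader_id", "day", "average_activation")],
    as.data.frame(profiles), by = "trader_id", all.x = TRUE)
  excluded <- ds[is.na(ds$experience_years), c("trader_id", "day")]
  if (nrow(excluded))
    message("excluding ", nrow(excluded), " trader-day(s) without profile match")
  ds <- ds[!is.na(ds$experience_years), ]
  ds$day <- as.character(ds$day)
  key <- paste(ds$trader_id, ds$day)
  txkey <- paste(tx$trader_id, tx$day)
  ds$numT <- as.numeric(tapply(rep(1, nrow(tx)), txkey, sum)[key])
  ds$numT[is.na(ds$numT)] <- 0
  amt <- tapply(tx$amount_usd, txkey, mean)[key] / amt_scale
  ds$amt <- ifelse(is.na(amt), 0, as.numeric(amt))
  if (!is.null(markets)) {
    if (length(markets) && !inherits(markets[[1]], "market_series"))
      markets <- unlist(markets, recursive = FALSE)
    volrows <- do.call(rbind, lapply(markets, function(m) {
      d <- split(m$values, as.character(day_of(m$timestamps)))
      do.call(rbind, lapply(names(d), function(dd)
        data.frame(index_name = m$index_name, day = dd,
                   vol = if (length(d[[dd]]) > 2) sd(diff(d[[dd]])) else NA_real_)))
    }))
    for (ix in unique(volrows$index_name)) {
      v <- volrows[volrows$index_name == ix, ]
      col <- paste0("vol_", gsub("[^A-Za-z0-9]+", "_", ix))
      ds[[col]] <- v$vol[match(ds$day, v$day)]
    }
  }
  names(ds)[names(ds) == "average_activation"] <- "y"
  rownames(ds) <- NULL
  class(ds) <- c("attribution_dataset", "data.frame")
  attr(ds, "excluded") <- excluded
  ds
}

#' Fit the attribution regression
#'
#' Ordinary least squares of average activation on the one-hot-encoded
#' business division (first level alphabetically is the reference), binary
#' gender, mean transaction amount, trading experience, transaction count and
#' the per-index volatility columns, with an intercept. Classical
#' standard errors by default; `cluster = TRUE` uses cluster-robust
#' (by trader) errors via the sandwich estimator.
#'
#' @param ds an `attribution_dataset` from [build_dataset()].
#' @param cluster cluster standard errors by trader (needs the
#'   `sandwich` and `lmtest` packages).
#' @param log_amount model `log1p(amt)` instead of raw `amt`.
#' @return object of class `attribution_result`: `coefficients` table
#'   (estimate, std.error, t, p), `n`, `r_squared`, and the underlying `fit`.
#' @export
fit_attribution <- function(ds, cluster = FALSE, log_amount = FALSE) {
  stopifnot(inherits(ds, "data.frame"))
  volcols <- grep("^vol_", names(ds), value = TRUE)
  ds <- as.data.frame(ds)
  ds$division <- factor(ds$division)
  ds$gender <- factor(ds$gender)
  if (log_amount) ds$amt <- log1p(ds$amt)
  terms <- c(if (nlevels(ds$division) > 1) "division",
             if (nlevels(ds$gender) > 1) "gender",
             "amt", "experience_years", "numT", volcols)
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, ds)
  if (nrow(X) <= ncol(X))
    stop_ppactiv("not enough rows (", nrow(X), ") for ", ncol(X),
                 " design columns", class = "ppactiv_validation")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_ppactiv("rank-deficient design; collinear column(s): ",
                 paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                       collapse = ", "),
                 class = "ppactiv_validation")
  fit <- lm(fml, data = ds)
  if (cluster) {
    if (!requireNamespace("sandwich", quietly = TRUE) ||
        !requireNamespace("lmtest", quietly = TRUE))
      stop_ppactiv("cluster SEs need the sandwich and lmtest packages",
                   class = "ppactiv_config")
    vc <- sandwich::vcovCL(fit, cluster = ds$trader_id)
    ct <- lmtest::coeftest(fit, vcov. = vc)
    coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                        std.error = ct[, 2], statistic = ct[, 3],
                        p_value = ct[, 4], row.names = NULL)
  } else {
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std.error = sm[, 2], statistic = sm[, 3],
                        p_value = sm[, 4], row.names = NULL)
  }
  structure(list(coefficients = coefs, n = nrow(ds),
                 r_squared = summary(fit)$r.squared, fit = fit),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}
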