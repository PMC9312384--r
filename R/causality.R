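# Granger causality between market-index fluctuations and activation.
#
# The 1 Hz activation series is frequency-averaged to calendar minutes, both
# series are first-differenced for stationarity, and the null "the index
# fluctuations do not Granger-cause activation" is tested with the SSR
# chi-square statistic: n_eff * (SSR_restricted - SSR_unrestricted) /
# SSR_unrestricted with lag-order degrees of freedom. Family-wise error over
# traders is controlled per index with Holm-Bonferroni; a Kolmogorov-Smirnov
# uniformity check on the raw p-values diagnoses departures from the global
# null.

#' Align a trader-day activation series with a market index at minute level
#'
#' Averages the valid 1 Hz activation samples within each calendar minute
#' (`floor(epoch / 60)`), intersects with the market minutes, and returns the
#' aligned first differences of both series. Differences are only taken
#' between adjacent calendar minutes; partial leading/trailing minutes of the
#' activation grid are dropped.
#'
#' @param act an `activation_series`.
#' @param mkt a [market_series()].
#' @param min_minutes minimum number of common minutes required.
#' @return list `(dy, dm, minutes)` of aligned first differences, or an error
#'   of class `ppactiv_skip` when the overlap is insufficient.
#' @export
prepare_pair <- function(act, mkt, min_minutes = 30) {
  stopifnot(inherits(act, "activation_series"), inherits(mkt, "market_series"))
  minute <- floor(act$timestamps / 60)
  m0 <- min(minute)
  mi <- minute - m0 + 1
  nb <- max(mi)
  cnt_all <- tabulate(mi, nbins = nb)   # grid seconds per minute
  ok <- act$valid & !is.na(act$dM)
  cnt_ok <- tabulate(mi[ok], nbins = nb)
  sum_ok <- numeric(nb)
  if (any(ok)) {
    s <- rowsum(act$dM[ok], mi[ok])
    sum_ok[as.integer(rownames(s))] <- s[, 1]
  }
  usable <- cnt_all == 60 & cnt_ok >= 1  # full minutes with valid samples
  ymin <- (seq_len(nb) - 1 + m0)[usable]
  ybar <- (sum_ok / pmax(cnt_ok, 1))[usable]
  mmin <- floor(mkt$timestamps / 60)
  common <- intersect(ymin, mmin)
  if (length(common) < max(2, min_minutes))
    stop_ppactiv("insufficient overlap: ", length(common), " common minutes",
                 class = "ppactiv_skip")
  common <- sort(common)
  y <- ybar[match(common, ymin)]
  m <- mkt$values[match(common, mmin)]
  adj <- diff(common) == 1
  list(dy = diff(y)[adj], dm = diff(m)[adj], minutes = common[-1][adj])
}

#' Granger SSR chi-square test
#'
#' Regresses `dy_t` on a constant and its own lags `1..p` (restricted), then
#' adds lags `1..p` of `dm` (unrestricted). The statistic is
#' `n_eff * (SSR_r - SSR_u) / SSR_u`, referred to a chi-square distribution
#' with `p` degrees of freedom, where `n_eff` is the number of usable rows
#' after lag embedding.
#'
#' @param dy differenced minute-level activation.
#' @param dm differenced minute-level market index, same length.
#' @param lag_order lag order `p` (default 10 minutes).
#' @return object of class `granger_result`: `statistic`, `df`, `p_value`,
#'   `n_obs`, `lag_order`.
#' @export
granger_ssr_test <- function(dy, dm, lag_order = 10) {
  stopifnot(length(dy) == length(dm), lag_order >= 1)
  p <- as.integer(lag_order)
  n <- length(dy)
  if (n - p < 3 * p)
    stop_ppactiv("series too short for lag order ", p, " (", n, " rows)",
                 class = "ppactiv_skip")
  idx <- (p + 1):n
  lagmat <- function(x) sapply(1:p, function(k) x[idx - k])
  Yt <- dy[idx]
  Xr <- cbind(1, lagmat(dy))
  Xu <- cbind(Xr, lagmat(dm))
  qu <- qr(Xu)
  if (qu$rank < ncol(Xu))
    stop_ppactiv("degenerate design: collinear or constant regressor block",
                 class = "ppactiv_degenerate")
  ssr <- function(X) {
    r <- qr.resid(qr(X), Yt)
    sum(r^2)
  }
  ssr_u <- ssr(Xu)
  ssr_r <- ssr(Xr)
  if (ssr_u <= 0)
    stop_ppactiv("degenerate design: perfect fit in unrestricted model",
                 class = "ppactiv_degenerate")
  n_eff <- length(Yt)
  stat <- n_eff * (ssr_r - ssr_u) / ssr_u
  structure(list(statistic = stat, df = p,
                 p_value = pchisq(stat, p, lower.tail = FALSE),
                 n_obs = n_eff, lag_order = p),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger SSR chi2 = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_obs))
  invisible(x)
}

#' Holm-Bonferroni step-down rejections
#'
#' Sorts the p-values ascending and rejects `p_(k)` while
#' `p_(k) <= alpha / (m - k + 1)`, stopping at the first failure; flags are
#' returned in the input order. Implemented through
#' `stats::p.adjust(method = "holm")`, which is algebraically the same rule.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha family-wise significance level (default 0.05).
#' @return logical rejection flags aligned with `p_values`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical())
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_ppactiv("p-values must lie in [0, 1]", class = "ppactiv_validation")
  p.adjust(p_values, method = "holm") <= alpha
}

#' One-sample Kolmogorov-Smirnov uniformity test for p-values
#'
#' `D = sup |F_n(x) - x|` against the uniform CDF on `[0, 1]`, with the
#' p-value from the asymptotic Kolmogorov distribution of `sqrt(n) D`.
#'
#' @param p_values numeric vector in `[0, 1]`, length >= 1.
#' @return list `(D, p_value, n)`.
#' @export
ks_uniformity <- function(p_values) {
  if (!length(p_values))
    stop_ppactiv("need at least one p-value", class = "ppactiv_validation")
  if (any(p_values < 0 | p_values > 1))
    stop_ppactiv("p-values must lie in [0, 1]", class = "ppactiv_validation")
  kt <- suppressWarnings(ks.test(p_values, "punif", exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value, n = length(p_values))
}

#' Scan all trader-day x index pairs for Granger causality
#'
#' Runs [granger_ssr_test()] on every pair, applies Holm-Bonferroni within
#' each index family (pooling all trader-days of that index), and attaches
#' per-index significant counts and KS uniformity diagnostics. Pairs with
#' insufficient overlap or degenerate designs are skipped and logged, never
#' fatal.
#'
#' @param acts list of `activation_series` (one per trader-day).
#' @param mkts list of [market_series()]; a nested list (one inner list per
#'   day, as produced by the synthetic generator) is flattened and matched to
#'   each activation series by day via timestamp overlap.
#' @param config list: `lag_order` (default 10), `alpha` (default 0.05),
#'   `min_minutes` passed to [prepare_pair()].
#' @return object of class `granger_scan`: `results` (per-test rows with
#'   Holm-corrected `reject` flags), `per_index` summary (n tests,
#'   significant count, KS D and p), and `skipped`.
#' @export
causality_scan <- function(acts, mkts, config = list()) {
  lag_order <- config$lag_order %||% 10
  alpha <- config$alpha %||% 0.05
  min_minutes <- config$min_minutes %||% (lag_order + 20)
  if (!length(acts) || !length(mkts))
    stop_ppactiv("need at least one activation series and one market series",
                 class = "ppactiv_validation")
  if (!inherits(mkts[[1]], "market_series")) mkts <- unlist(mkts, recursive = FALSE)
  rows <- list(); skipped <- list()
  for (act in acts) {
    span <- range(act$timestamps)
    for (mkt in mkts) {
      if (mkt$timestamps[length(mkt$timestamps)] < span[1] ||
          mkt$timestamps[1] > span[2]) next  # different day
      res <- tryCatch({
        pair <- prepare_pair(act, mkt, min_minutes)
        g <- granger_ssr_test(pair$dy, pair$dm, lag_order)
        data.frame(trader_id = act$trader_id, day = as.character(act$day),
                   index_name = mkt$index_name, lag_order = g$lag_order,
                   statistic = g$statistic, df = g$df, p_value = g$p_value,
                   n_obs = g$n_obs)
      }, ppactiv_skip = function(e) e, ppactiv_degenerate = function(e) e)
      if (is.data.frame(res)) {
        rows[[length(rows) + 1]] <- res
      } else {
        skipped[[length(skipped) + 1]] <- data.frame(
          trader_id = act$trader_id, day = as.character(act$day),
          index_name = mkt$index_name, reason = conditionMessage(res))
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trader_id = character(), day = character(),
               index_name = character(), lag_order = integer(),
               statistic = numeric(), df = integer(), p_value = numeric(),
               n_obs = integer())
  results$reject <- FALSE
  per_index <- list()
  for (ix in unique(results$index_name)) {
    sel <- results$index_name == ix
    rej <- holm_bonferroni(results$p_value[sel], alpha)
    results$reject[sel] <- rej
    ks <- ks_uniformity(results$p_value[sel])
    per_index[[ix]] <- data.frame(index_name = ix, n_tests = sum(sel),
                                  n_significant = sum(rej),
                                  ks_D = ks$D, ks_p = ks$p_value)
  }
  structure(list(
    results = results,
    per_index = if (length(per_index)) do.call(rbind, c(per_index, make.row.names = FALSE)) else
      data.frame(index_name = character(), n_tests = integer(),
                 n_significant = integer(), ks_D = numeric(), ks_p = numeric()),
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(trader_id = character(), day = character(),
                 index_name = character(), reason = character()),
    alpha = alpha, lag_order = lag_order),
    class = "granger_scan")
}

#' @export
print.granger_scan <- function(x, ...) {
  cat(sprintf("<granger_scan> %d tests, %d skipped, lag %d, alpha %.2f\n",
              nrow(x$results), nrow(x$skipped), x$lag_order, x$alpha))
  print(x$per_index, row.names = FALSE)
  invisible(x)
}
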