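# Psychophysiological activation scoring.
#
# The activation of a feature vector y_t is the squared Mahalanobis distance
#   d_M(y_t) = (y_t - mu_t)' Sigma_t^{-1} (y_t - mu_t)
# where mu_t and Sigma_t are the sample mean and covariance of y_1, ..., y_t
# (expanding window from the day's start through t, so the score at t never
# uses future samples and carries no look-ahead bias).

#' Expanding sample moments of a feature series
#'
#' Batch (brute-force) mean and sample covariance (denominator n - 1) of all
#' valid feature rows from the start of the day up to and including time `t`.
#' The streaming path used by [activation_series()] must agree with this to
#' numerical precision; this function is the reference.
#'
#' @param features a `feature_series` from [assemble_feature_series()], or any
#'   list with `timestamps`, `matrix`, `valid`.
#' @param t evaluation time (epoch seconds).
#' @param min_history minimum number of valid rows required.
#' @param columns optional subset of feature columns.
#' @return list `(mu, sigma, n)`.
#' @export
expanding_moments <- function(features, t, min_history = 2, columns = NULL) {
  sel <- features$valid & features$timestamps <= t
  Y <- features$matrix[sel, columns %||% seq_len(ncol(features$matrix)),
                       drop = FALSE]
  n <- nrow(Y)
  if (n < max(2, min_history))
    stop_ppactiv("insufficient history at t (", n, " valid rows)",
                 class = "ppactiv_burnin")
  list(mu = colMeans(Y), sigma = stats::cov(Y), n = n)
}

#' Squared Mahalanobis activation of one feature vector
#'
#' Computes `(y - mu)' (Sigma + eps * mean(diag(Sigma)) I)^{-1} (y - mu)`,
#' the squared Mahalanobis form. The relative ridge `eps` guards against
#' early-day singular covariances (for instance while the integer SCR count
#' is still constant); `eps = 0` gives the exact quadratic form.
#'
#' @param y feature vector.
#' @param mu mean vector.
#' @param sigma covariance matrix.
#' @param ridge relative ridge coefficient (default 0).
#' @return non-negative scalar activation.
#' @export
mahalanobis_activation <- function(y, mu, sigma, ridge = 0) {
  d <- length(y)
  stopifnot(length(mu) == d, all(dim(sigma) == d))
  dev <- as.numeric(y - mu)
  if (all(dev == 0)) return(0)
  md <- mean(diag(sigma))
  S <- sigma + ridge * (if (md > 0) md else 1) * diag(d)
  sol <- tryCatch(solve(S, dev), error = function(e)
    stop_ppactiv("covariance singular after regularization (rcond = ",
                 signif(rcond(S), 3), ")", class = "ppactiv_numerical"))
  max(sum(dev * sol), 0)
}

# reference R implementation of the streaming scorer (used as an oracle and
# as a fallback); mirrors stream_mahal_cpp exactly
stream_mahal_r <- function(Y, valid, min_history, ridge_frac) {
  n <- nrow(Y); d <- ncol(Y)
  mu <- numeric(d); C <- matrix(0, d, d)
  out <- rep(NA_real_, n)
  k <- 0
  for (i in seq_len(n)) {
    if (!isTRUE(valid[i])) next
    y <- Y[i, ]
    k <- k + 1
    delta <- y - mu
    mu <- mu + delta / k
    C <- C + tcrossprod(delta, y - mu)
    if (k < min_history) next
    S <- C / (k - 1)
    md <- mean(diag(S))
    eps <- ridge_frac * (if (md > 0) md else 1)
    dev <- y - mu
    v <- sum(dev * solve(S + eps * diag(d), dev))
    out[i] <- max(v, 0)
  }
  out
}

#' Score a day's activation series
#'
#' Runs the streaming expanding-moment Mahalanobis scorer over the valid rows
#' of a feature series, then attaches the day-level mean and standard
#' deviation of activation and the z-scored series. `mode` selects the
#' feature columns: `"overall"` uses all eleven; `"hrv"`, `"eda"`, `"bvp"`,
#' `"temp"` use one physiological family, giving the per-family activation
#' measures.
#'
#' @param features a `feature_series`.
#' @param mode `"overall"` or one of `names(ppactiv_families)`.
#' @param config list: `min_history` (valid rows of burn-in, default
#'   `max(300, 5 * d)`), `ridge` (relative ridge, default `1e-6`),
#'   `engine` (`"cpp"` or `"r"`).
#' @return object of class `activation_series` with fields `timestamps`,
#'   `dM`, `valid`, `z`, `day_mean`, `day_sd`, `mode`, `trader_id`, `day`.
#' @export
activation_series <- function(features,
                              mode = c("overall", "hrv", "eda", "bvp", "temp"),
                              config = list()) {
  mode <- match.arg(mode)
  Y <- if (mode == "overall") features$matrix else
    features$matrix[, ppactiv_families[[mode]], drop = FALSE]
  d <- ncol(Y)
  min_history <- config$min_history %||% max(300, 5 * d)
  ridge <- config$ridge %||% 1e-6
  engine <- config$engine %||% "cpp"
  if (!any(features$valid))
    stop_ppactiv("no valid feature rows; cannot score activation",
                 class = "ppactiv_empty")
  Y0 <- Y
  Y0[is.na(Y0)] <- 0  # invalid rows are skipped; zeros never enter moments
  dM <- if (engine == "cpp") {
    stream_mahal_cpp(Y0, features$valid, as.integer(min_history), ridge)
  } else {
    stream_mahal_r(Y0, features$valid, min_history, ridge)
  }
  valid <- features$valid & !is.na(dM)
  mu <- mean(dM[valid])
  sigma <- sd(dM[valid])
  z <- rep(NA_real_, length(dM))
  if (isTRUE(sigma > 0)) z[valid] <- (dM[valid] - mu) / sigma
  structure(list(trader_id = features$trader_id, day = features$day,
                 timestamps = features$timestamps, dM = dM, valid = valid,
                 day_mean = mu, day_sd = sigma, z = z, mode = mode),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  cat(sprintf("<activation_series> trader %s, %s (%s): %d valid rows, day mean %.2f, sd %.2f\n",
              x$trader_id, format(x$day), x$mode, sum(x$valid), x$day_mean, x$day_sd))
  invisible(x)
}

#' Label mild and extreme activation episodes
#'
#' A sample is mildly activated when `dM > mu + 1.5 sigma` and extremely
#' activated when `dM > mu + 3 sigma`, where `mu` and `sigma` are the day's
#' mean and standard deviation of activation. Episodes are maximal contiguous
#' runs of consecutive valid 1 Hz samples above a level's threshold; gaps are
#' never merged. A zero-variance day yields no episodes.
#'
#' @param act an `activation_series`.
#' @param thresholds named numeric, standard-deviation multipliers for each
#'   level (default `c(mild = 1.5, extreme = 3)`).
#' @return data.frame with columns `level`, `start`, `end` (epoch seconds of
#'   first/last sample above threshold) and `duration_s` (number of 1 Hz grid
#'   samples in the run).
#' @export
label_episodes <- function(act, thresholds = c(mild = 1.5, extreme = 3)) {
  stopifnot(inherits(act, "activation_series"))
  out <- data.frame(level = character(), start = numeric(), end = numeric(),
                    duration_s = numeric())
  if (!isTRUE(act$day_sd > 0)) {
    message("degenerate day (sd = 0): no activation episodes")
    return(out)
  }
  for (lev in names(thresholds)) {
    thr <- act$day_mean + thresholds[[lev]] * act$day_sd
    flag <- act$valid & !is.na(act$dM) & act$dM > thr
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      out <- rbind(out, data.frame(
        level = lev,
        start = act$timestamps[starts[keep]],
        end = act$timestamps[ends[keep]],
        duration_s = r$lengths[keep]))
  }
  out
}

#' Summarize one trader-day's activation
#'
#' Average activation is the mean of `dM` over valid samples; the mild and
#' extreme proportions are the percentage of valid samples above the
#' respective thresholds (mild includes extreme); activation length is the
#' mean duration in seconds of the mild episodes (0 if there are none).
#'
#' @param act an `activation_series`.
#' @param episodes output of [label_episodes()]; computed if missing.
#' @return one-row data.frame of class `activation_summary`.
#' @export
summarize_day <- function(act, episodes = NULL) {
  stopifnot(inherits(act, "activation_series"))
  if (is.null(episodes)) episodes <- label_episodes(act)
  nv <- sum(act$valid)
  if (nv == 0)
    stop_ppactiv("empty activation series", class = "ppactiv_empty")
  dM <- act$dM[act$valid]
  prop <- function(k) {
    if (!isTRUE(act$day_sd > 0)) return(0)
    100 * sum(dM > act$day_mean + k * act$day_sd) / nv
  }
  mild_ep <- episodes[episodes$level == "mild", , drop = FALSE]
  df <- data.frame(trader_id = act$trader_id, day = act$day,
                   average_activation = mean(dM),
                   mild_proportion = prop(1.5),
                   extreme_proportion = prop(3),
                   activation_length_s = if (nrow(mild_ep)) mean(mild_ep$duration_s) else 0,
                   n_valid = nv)
  class(df) <- c("activation_summary", "data.frame")
  df
}

#' Cohort histograms and summary statistics of the activation metrics
#'
#' Pools trader-day summaries and returns, for each of the four activation
#' metrics, histogram counts plus a min/max/mean/sd table across trader-days.
#'
#' @param summaries data.frame of row-bound [summarize_day()] outputs.
#' @param breaks number of histogram cells (passed to [graphics::hist()]).
#' @return object of class `histogram_set`: per-metric `breaks`/`counts` and a
#'   `stats` table.
#' @export
cohort_histograms <- function(summaries, breaks = 30) {
  stopifnot(nrow(summaries) >= 1)
  metrics <- c("average_activation", "mild_proportion", "extreme_proportion",
               "activation_length_s")
  hists <- lapply(metrics, function(m) {
    h <- graphics::hist(summaries[[m]], breaks = breaks, plot = FALSE)
    list(metric = m, breaks = h$breaks, counts = h$counts)
  })
  names(hists) <- metrics
  stats <- do.call(rbind, lapply(metrics, function(m) {
    x <- summaries[[m]]
    data.frame(metric = m, min = min(x), max = max(x), mean = mean(x),
               sd = if (length(x) > 1) sd(x) else 0)
  }))
  structure(list(histograms = hists, stats = stats,
                 n_trader_days = nrow(summaries)),
            class = "histogram_set")
}

#' Export an activation series as CSV
#'
#' Columns: timestamp, dM, z, mild and extreme flags.
#'
#' @param act an `activation_series`.
#' @param path destination file.
#' @export
write_activation_csv <- function(act, path) {
  mild <- extreme <- rep(FALSE, length(act$dM))
  if (isTRUE(act$day_sd > 0)) {
    mild <- act$valid & act$dM > act$day_mean + 1.5 * act$day_sd
    extreme <- act$valid & act$dM > act$day_mean + 3 * act$day_sd
  }
  df <- data.frame(timestamp = act$timestamps, dM = act$dM, z = act$z,
                   mild = mild, extreme = extreme, valid = act$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
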