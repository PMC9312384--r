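#' @useDynLib ppactiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef ks.test lm p.adjust pchisq pt qchisq rbinom
#'   rexp rlnorm rnorm rpois runif sd setNames var
#' @importFrom utils modifyList read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ppactiv <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ppactiv_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic 32-bit integer mixing for sub-seeds; keeps every derived seed
# in [0, 2^31) so set.seed() accepts it on all platforms
mix_seed <- function(master, ...) {
  parts <- c(master, ...)
  h <- 0
  for (v in parts) {
    h <- (h * 69069 + (as.numeric(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# sliding min/max over a fixed window of w samples, aligned to the window END
# index; positions 1..(w-1) are NA. O(n) block prefix/suffix scan.
rolling_extreme <- function(x, w, op = c("min", "max")) {
  op <- match.arg(op)
  f <- if (op == "min") cummin else cummax
  n <- length(x)
  if (w <= 1L) return(x)
  if (n < w) return(rep(NA_real_, n))
  nb <- ceiling(n / w)
  pad <- nb * w - n
  xp <- c(x, rep(if (op == "min") Inf else -Inf, pad))
  m <- matrix(xp, nrow = w)
  pre <- apply(m, 2, f)                       # prefix within block
  suf <- apply(m[w:1, , drop = FALSE], 2, f)[w:1, , drop = FALSE]
  pre <- as.vector(pre); suf <- as.vector(suf)
  e <- w:n
  s <- e - w + 1L
  out <- rep(NA_real_, n)
  same_block <- ((s - 1L) %/% w) == ((e - 1L) %/% w)
  comb <- if (op == "min") pmin else pmax
  out[e] <- ifelse(same_block, pre[e], comb(suf[s], pre[e]))
  out
}

# extreme of each consecutive block of `block` samples (pads the tail)
block_extreme <- function(x, block, op = c("min", "max")) {
  op <- match.arg(op)
  pad <- ceiling(length(x) / block) * block - length(x)
  m <- matrix(c(x, rep(if (op == "min") Inf else -Inf, pad)), nrow = block)
  comb <- if (op == "min") pmin else pmax
  out <- m[1, ]
  for (r in seq_len(block)[-1]) out <- comb(out, m[r, ])
  out
}

# trailing rolling sum of x over windows of w samples, aligned to window end
rolling_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  out[w:n] <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  out
}
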