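#' @keywords internal
"_PACKAGE"

## Gaussian kernel smoothing with truncated (not padded) edges.
## Each output sample is renormalized by the kernel mass that fell inside the
## array, so a constant map stays constant and no mass is fabricated at edges.
gaussian_smooth <- function(x, sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  n <- length(x)
  lags <- -radius:radius
  k <- exp(-lags^2 / (2 * sigma^2))
  out <- numeric(n)
  na <- is.na(x)
  for (i in seq_len(n)) {
    j <- i + lags
    ok <- j >= 1L & j <= n
    jj <- j[ok]
    kk <- k[ok]
    use <- !na[jj]
    out[i] <- if (any(use)) sum(x[jj][use] * kk[use]) / sum(kk[use]) else NA_real_
  }
  out
}

## Windowed percentile, truncated at the trace edges (no padding).
## Percentiles use linear interpolation between order statistics (type = 7).
rolling_percentile <- function(x, half_width, p) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    out[i] <- stats::quantile(x[lo:hi], p / 100, names = FALSE, type = 7)
  }
  out
}

## Deterministic sub-seed derivation: keeps derived seeds valid 32-bit ints.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
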