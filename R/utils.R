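# shared internal numerics: boundary handling, smoothing, run detection

# half-sample symmetric reflection of indices onto 1..n (period 2n);
# works for any integer offset, so pads longer than the signal are fine
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Gaussian low-pass with reflective boundaries; sigma in samples.
# Kernel is normalized, so constants are reproduced exactly and the
# operator is doubly stochastic (mean-preserving) under symmetric padding.
gaussian_smooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 2L) {
    return(x)
  }
  rad <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq.int(-rad, rad), sd = sigma)
  k <- k / sum(k)
  xp <- x[reflect_index(seq.int(1L - rad, n + rad), n)]
  convolve(xp, k, type = "filter")
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# logical vector of length(x) - w + 1; TRUE where x[t..t+w-1] are all TRUE
runs_all <- function(x, w) {
  n <- length(x)
  if (n < w) {
    return(logical(0))
  }
  cs <- cumsum(x)
  (cs[w:n] - c(0, cs)[seq_len(n - w + 1L)]) == w
}

# Reporting rule for tensions: round to two decimals, then truncate toward
# zero at one decimal. Reproduces the printed values at both pressure levels
# (13.699 -> 13.7, 11.599 -> 11.6, 8.366 -> 8.3, 6.266 -> 6.2).
report_one_decimal <- function(x) {
  r2 <- round(x, 2)
  trunc(r2 * 10 + sign(r2) * 1e-6) / 10
}

stop_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
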