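#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is used when `length(a) * length(b) <= 400` and the pooled
#' sample is tie-free; otherwise the normal approximation with midrank tie
#' correction and continuity correction is applied.
#'
#' @param a,b Numeric samples (non-empty).
#'
#' @return One-row tibble with `u` (the U statistic of sample `a`),
#'   `p_value`, `n_a`, `n_b` and `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
mann_whitney_two_sided <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) * length(b) <= 400
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector (non-empty).
#'
#' @return One-row tibble `n`, `mean`, `sem` where `sem = sd / sqrt(n)` with
#'   the sample (n - 1) standard deviation, and `sem = 0` for `n = 1`.
#' @export
sample_summary <- function(values) {
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  n <- length(values)
  tibble(
    n = n,
    mean = mean(values),
    sem = if (n > 1) sd(values) / sqrt(n) else 0
  )
}

#' Pearson colocalization coefficient of two channels
#'
#' @param ch1,ch2 Numeric matrices of identical size (or numeric vectors).
#' @param mask Optional logical mask selecting the pixels to correlate; at
#'   least 3 pixels with nonzero variance in both channels are required.
#'
#' @return Pearson correlation in `[-1, 1]`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  if (!identical(dim(ch1), dim(ch2)) || length(ch1) != length(ch2)) {
    stop("`ch1` and `ch2` must have the same shape", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(ch1))
  x <- as.vector(ch1)[as.vector(mask)]
  y <- as.vector(ch2)[as.vector(mask)]
  if (length(x) < 3L) {
    stop("mask must select at least 3 pixels", call. = FALSE)
  }
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    stop("zero variance in a channel; Pearson r is undefined", call. = FALSE)
  }
  cor(x, y)
}

#' Per-field viability in percent
#'
#' @param live_counts,total_counts Integer vectors of equal length, one entry
#'   per field of view; `0 <= live <= total`, `total > 0`.
#'
#' @return [sample_summary()] of the per-field percentages
#'   `100 * live / total`.
#' @export
viability_percent <- function(live_counts, total_counts) {
  if (length(live_counts) != length(total_counts)) {
    stop("count vectors must have the same length", call. = FALSE)
  }
  if (any(total_counts <= 0)) stop("`total_counts` must be > 0", call. = FALSE)
  if (any(live_counts < 0) || any(live_counts > total_counts)) {
    stop("`live_counts` must lie in [0, total_counts]", call. = FALSE)
  }
  sample_summary(100 * live_counts / total_counts)
}

#' Per-field ratio of inhibitory to excitatory synaptic puncta
#'
#' @param vgat_counts,vglut_counts Puncta counts per field of view for the
#'   inhibitory (VGAT) and excitatory (VGLUT1) markers; `vglut_counts > 0`.
#'
#' @return [sample_summary()] of the per-field ratios `vgat / vglut`.
#' @export
synapse_ratio <- function(vgat_counts, vglut_counts) {
  if (length(vgat_counts) != length(vglut_counts)) {
    stop("count vectors must have the same length", call. = FALSE)
  }
  if (any(vglut_counts <= 0)) stop("`vglut_counts` must be > 0", call. = FALSE)
  sample_summary(vgat_counts / vglut_counts)
}
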