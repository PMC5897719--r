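#' Estimate the slow-varying fluorescence baseline F0
#'
#' A heavy linear-diffusion low-pass of the raw trace. The cumulative
#' diffusion time is chosen so the equivalent kernel is a Gaussian of
#' `sigma = window_s / 4` seconds — the `+/- 2 sigma` extent of the kernel
#' then spans the stated time window. Boundaries are reflective, so constants
#' are reproduced exactly, the mean is conserved, and interior linear trends
#' pass through unchanged. A strictly positive input yields a strictly
#' positive baseline (the output is a convex combination of input samples).
#'
#' @param f_raw Numeric vector of raw fluorescence (length >= 2).
#' @param frame_rate_hz Acquisition rate in Hz.
#' @param window_s Time window in seconds (default 30).
#'
#' @return Numeric vector `f0` of the same length.
#' @export
estimate_baseline <- function(f_raw, frame_rate_hz, window_s = 30) {
  if (length(f_raw) < 2L) stop("trace must have length >= 2", call. = FALSE)
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be > 0", call. = FALSE)
  gaussian_smooth(f_raw, sigma = window_s / 4 * frame_rate_hz)
}

#' Baseline-normalize a fluorescence trace
#'
#' @param f_raw,f0 Numeric vectors of equal length; `f0` strictly positive.
#' @param roi_id Optional label used in error messages.
#'
#' @return `(f_raw - f0) / f0`, the dF/F0 trace.
#' @export
compute_dff <- function(f_raw, f0, roi_id = NULL) {
  if (length(f_raw) != length(f0)) {
    stop("`f_raw` and `f0` must have the same length", call. = FALSE)
  }
  if (any(f0 <= 0)) {
    stop(
      "non-positive baseline",
      if (!is.null(roi_id)) paste0(" for ROI ", roi_id),
      "; dF/F0 is undefined",
      call. = FALSE
    )
  }
  (f_raw - f0) / f0
}

#' De-noise a dF/F0 trace with a 1-D Perona-Malik filter
#'
#' Explicit anisotropic diffusion
#' `u <- u + step * d/dx( g(|du/dx|) du/dx )` with conductance
#' `g(s) = 1 / (1 + (s / kappa)^2)` and reflective (zero-flux) boundaries.
#' Gradients well below `kappa` are diffused like linear smoothing while
#' gradients above `kappa` are preserved, so calcium transients keep their
#' sharp rise. The scheme is conservative (the mean is preserved exactly) and
#' satisfies a maximum principle for `step <= 0.5`: no new extrema are
#' created.
#'
#' @param dff Numeric dF/F0 trace.
#' @param kappa Conductance scale in dF/F0-per-frame units. Defaults to
#'   3 times the MAD-based noise estimate of `diff(dff)`, which adapts the
#'   edge threshold to the trace's own noise level.
#' @param n_iter Number of diffusion iterations (>= 0; 0 returns the input).
#' @param step Time step of the explicit scheme, in `(0, 0.5]`.
#'
#' @return Smoothed trace of the same length.
#' @export
smooth_perona_malik <- function(dff, kappa = NULL, n_iter = 10, step = 0.25) {
  if (n_iter < 0) stop("`n_iter` must be >= 0", call. = FALSE)
  if (step <= 0 || step > 0.5) {
    stop("`step` must lie in (0, 0.5] for stability", call. = FALSE)
  }
  if (is.null(kappa)) kappa <- 3 * mad(diff(dff))
  if (length(dff) < 3L || n_iter == 0L) {
    return(dff)
  }
  if (kappa < 0) stop("`kappa` must be > 0", call. = FALSE)
  if (kappa == 0) {
    # noise-free trace: nothing to de-noise
    return(dff)
  }
  u <- dff
  for (i in seq_len(n_iter)) {
    d <- diff(u)
    flux <- d / (1 + (d / kappa)^2)
    u <- u + step * (c(flux, 0) - c(0, flux))
  }
  u
}

#' Normalize and de-noise extracted traces
#'
#' Tidy pipeline step: for each ROI in a long trace table (as returned by
#' [extract_traces()]), estimates the baseline, computes dF/F0 and appends a
#' Perona-Malik-smoothed copy.
#'
#' @param traces Tibble with columns `roi_id`, `frame`, `f_raw` (and
#'   optionally `time_s`), carrying a `frame_rate_hz` attribute, or pass
#'   `frame_rate_hz` explicitly.
#' @param frame_rate_hz Acquisition rate in Hz.
#' @inheritParams estimate_baseline
#' @inheritParams smooth_perona_malik
#'
#' @return The input tibble with columns `f0`, `dff` and `dff_smooth` added;
#'   class `ca_traces`.
#' @export
normalize_traces <- function(traces,
                             frame_rate_hz = attr(traces, "frame_rate_hz"),
                             window_s = 30, kappa = NULL,
                             n_iter = 10, step = 0.25) {
  if (is.null(frame_rate_hz)) {
    stop("`frame_rate_hz` is neither given nor attached to `traces`", call. = FALSE)
  }
  out <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      f0 = estimate_baseline(.data$f_raw, frame_rate_hz, window_s),
      dff = compute_dff(.data$f_raw, .data$f0, roi_id = .data$roi_id[1]),
      dff_smooth = smooth_perona_malik(.data$dff, kappa, n_iter, step)
    ) |>
    dplyr::ungroup()
  attr(out, "frame_rate_hz") <- frame_rate_hz
  class(out) <- c("ca_traces", class(out))
  out
}
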