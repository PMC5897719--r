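#' Parameters for a synthetic calcium-imaging movie
#'
#' Bundles and validates the knobs of [simulate_movie()]. The defaults emulate
#' spontaneous somatic calcium activity in a mature cortical culture imaged at
#' 65 Hz with an EMCCD camera: sparse bright somata on a smooth non-uniform
#' background, sparse Poisson-timed transients with a fast linear rise and an
#' exponential decay, and additive Gaussian read-out noise.
#'
#' @param n_cells Number of cells to render (>= 0).
#' @param height,width Frame size in pixels.
#' @param duration_s Movie duration in seconds (> 0).
#' @param frame_rate_hz Acquisition rate in Hz (default 65).
#' @param cell_radius_px Nominal soma radius in pixels; the rendered intensity
#'   profile is a 2-D Gaussian with `sigma = cell_radius_px / 2`, so the
#'   radius corresponds to the 2-sigma disk.
#' @param event_rate_hz Per-cell Poisson rate of calcium events (events/s).
#' @param amplitude_dff Peak dF/F0 of a single transient.
#' @param decay_tau_s Exponential decay time constant of a transient (s).
#' @param rise_frames Length of the linear rise, in frames.
#' @param baseline_level Baseline fluorescence of the field (a.u.); with no
#'   cells, no noise and no gradient every frame equals this constant.
#' @param background_gradient Slope of the static background plane
#'   (a.u. per pixel of row + column index).
#' @param resting_contrast Static extra brightness of a soma at rest,
#'   relative to `baseline_level` (peak of the Gaussian profile).
#' @param noise_sd Standard deviation of the additive Gaussian noise (a.u.).
#' @param min_separation_px Minimum center-to-center distance between cells;
#'   defaults to `4 * cell_radius_px` so that detected ROIs do not merge.
#' @param seed Integer seed; the simulation is bit-reproducible given the seed.
#'
#' @return A `movie_sim_params` list.
#' @export
#' @examples
#' p <- movie_sim_params(n_cells = 3, duration_s = 20, seed = 1)
#' sim <- simulate_movie(p)
#' dim(sim$movie$frames)
movie_sim_params <- function(n_cells = 10,
                             height = 64,
                             width = 64,
                             duration_s = 60,
                             frame_rate_hz = 65,
                             cell_radius_px = 3,
                             event_rate_hz = 0.1,
                             amplitude_dff = 0.5,
                             decay_tau_s = 1,
                             rise_frames = 10,
                             baseline_level = 100,
                             background_gradient = 0.2,
                             resting_contrast = 0.5,
                             noise_sd = 1,
                             min_separation_px = 4 * cell_radius_px,
                             seed = 1L) {
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be > 0", call. = FALSE)
  if (height < 1 || width < 1) stop("frame dimensions must be >= 1 pixel", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (amplitude_dff < 0) stop("`amplitude_dff` must be >= 0", call. = FALSE)
  if (event_rate_hz < 0) stop("`event_rate_hz` must be >= 0", call. = FALSE)
  if (rise_frames < 1) stop("`rise_frames` must be >= 1", call. = FALSE)
  structure(
    list(
      n_cells = as.integer(n_cells), height = as.integer(height),
      width = as.integer(width), duration_s = duration_s,
      frame_rate_hz = frame_rate_hz, cell_radius_px = cell_radius_px,
      event_rate_hz = event_rate_hz, amplitude_dff = amplitude_dff,
      decay_tau_s = decay_tau_s, rise_frames = as.integer(rise_frames),
      baseline_level = baseline_level,
      background_gradient = background_gradient,
      resting_contrast = resting_contrast, noise_sd = noise_sd,
      min_separation_px = min_separation_px, seed = as.integer(seed)
    ),
    class = "movie_sim_params"
  )
}

#' Construct a calcium-imaging movie object
#'
#' @param frames Numeric array of dimension `height x width x n_frames`
#'   (frames along the third axis), nonnegative intensities in a.u.
#' @param frame_rate_hz Acquisition rate in Hz.
#'
#' @return A `ca_movie` object.
#' @export
ca_movie <- function(frames, frame_rate_hz) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (height x width x time)", call. = FALSE)
  }
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be > 0", call. = FALSE)
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz),
    class = "ca_movie"
  )
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<ca_movie> %d x %d px, %d frames @ %g Hz (%.1f s)\n",
    d[1], d[2], d[3], x$frame_rate_hz, d[3] / x$frame_rate_hz
  ))
  invisible(x)
}

# single-transient kernel: linear rise to `amplitude` over `rise_frames`,
# then exponential decay with time constant decay_tau_s
transient_kernel <- function(amplitude, rise_frames, decay_tau_s, frame_rate_hz) {
  decay_frames <- max(1L, as.integer(ceiling(6 * decay_tau_s * frame_rate_hz)))
  c(
    amplitude * seq_len(rise_frames) / rise_frames,
    amplitude * exp(-seq_len(decay_frames) / (decay_tau_s * frame_rate_hz))
  )
}

place_centers <- function(n, height, width, radius, min_sep) {
  if (n == 0L) {
    return(cbind(row = numeric(0), col = numeric(0)))
  }
  margin <- ceiling(2 * radius) + 1
  if (height - 2 * margin < 0 || width - 2 * margin < 0) {
    stop("frame too small for the requested cell radius", call. = FALSE)
  }
  for (restart in seq_len(200)) {
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < n && tries < 2000) {
      cand <- c(
        stats::runif(1, margin, height - margin + 1),
        stats::runif(1, margin, width - margin + 1)
      )
      tries <- tries + 1
      if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep)) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) == n) {
      colnames(centers) <- c("row", "col")
      rownames(centers) <- NULL
      return(centers)
    }
  }
  stop(
    "could not place ", n, " cells with the requested minimum separation; ",
    "enlarge the frame or reduce `min_separation_px`",
    call. = FALSE
  )
}

#' Simulate a calcium-imaging movie with known ground truth
#'
#' Renders `n_cells` somata as 2-D Gaussian intensity profiles
#' (`sigma = cell_radius_px / 2`) on a static field. A pixel's intensity is
#'
#' `baseline_level * (1 + profile * (resting_contrast + dF/F0(t))) +
#'  background_gradient * (row + col) + noise`,
#'
#' so at a soma center the fluorescence follows
#' `baseline * (1 + dF/F0(t))` on top of its resting brightness. The per-cell
#' dF/F0 trace is a sum of transient kernels (linear rise over `rise_frames`,
#' exponential decay with `decay_tau_s`) started at Poisson event times.
#' I.i.d. Gaussian noise is added and intensities are clipped at zero. The
#' background is static in time, so the standard-deviation projection is
#' background-free by construction while the projection path is still
#' exercised.
#'
#' @param params A [movie_sim_params()] object.
#'
#' @return A list with elements
#' \describe{
#'   \item{movie}{a [ca_movie()] (`height x width x n_frames` array).}
#'   \item{truth}{a tibble with one row per cell: 0-based `row`/`col` center,
#'     list-column `onsets` of 0-based event onset frames, `n_events`, and
#'     `true_mfr_hz = n_events / duration_s`.}
#' }
#' @export
simulate_movie <- function(params) {
  stopifnot(inherits(params, "movie_sim_params"))
  p <- params
  set.seed(p$seed)
  n_frames <- as.integer(round(p$duration_s * p$frame_rate_hz))
  if (n_frames < 2L) stop("movie must have at least 2 frames", call. = FALSE)

  centers <- place_centers(
    p$n_cells, p$height, p$width, p$cell_radius_px, p$min_separation_px
  )

  # per-cell event times (Poisson count, distinct uniform onset frames)
  onsets <- purrr::map(seq_len(p$n_cells), function(i) {
    n_ev <- rpois(1L, p$event_rate_hz * p$duration_s)
    n_ev <- min(n_ev, n_frames)
    sort(sample.int(n_frames, n_ev) - 1L) # 0-based
  })

  frames <- if (p$noise_sd > 0) {
    rnorm(p$height * p$width * n_frames, sd = p$noise_sd)
  } else {
    numeric(p$height * p$width * n_frames)
  }
  dim(frames) <- c(p$height, p$width, n_frames)
  bg <- p$baseline_level + p$background_gradient *
    outer(seq_len(p$height) - 1, seq_len(p$width) - 1, `+`)
  frames <- frames + as.vector(bg) # recycled over the time axis

  sigma <- p$cell_radius_px / 2
  kernel <- transient_kernel(
    p$amplitude_dff, p$rise_frames, p$decay_tau_s, p$frame_rate_hz
  )
  dim(frames) <- c(p$height * p$width, n_frames)
  for (i in seq_len(p$n_cells)) {
    dff <- numeric(n_frames)
    for (o in onsets[[i]]) {
      idx <- (o + 1L):min(n_frames, o + length(kernel))
      dff[idx] <- dff[idx] + kernel[seq_along(idx)]
    }
    rad <- ceiling(4 * sigma)
    rows <- max(1, floor(centers[i, 1] - rad)):min(p$height, ceiling(centers[i, 1] + rad))
    cols <- max(1, floor(centers[i, 2] - rad)):min(p$width, ceiling(centers[i, 2] + rad))
    d2 <- outer((rows - centers[i, 1])^2, (cols - centers[i, 2])^2, `+`)
    prof <- p$baseline_level * exp(-d2 / (2 * sigma^2))
    pix <- as.vector(outer(rows, (cols - 1L) * p$height, `+`))
    frames[pix, ] <- frames[pix, ] +
      outer(as.vector(prof), p$resting_contrast + dff)
  }
  frames[frames < 0] <- 0
  dim(frames) <- c(p$height, p$width, n_frames)

  truth <- tibble(
    cell = seq_len(p$n_cells),
    row = centers[, "row"] - 1, # 0-based
    col = centers[, "col"] - 1,
    onsets = onsets,
    n_events = vapply(onsets, length, integer(1)),
    true_mfr_hz = vapply(onsets, length, integer(1)) / p$duration_s
  )

  list(movie = ca_movie(frames, p$frame_rate_hz), truth = truth)
}

#' Simulate a pressure-clamp recording with a channel-opening current step
#'
#' Emulates a cell-attached recording during a linear suction ramp: the
#' pressure (stored as a positive suction magnitude in mmHg) increases from 0
#' at `ramp_rate_mmhg_s`, and the current is Gaussian noise plus a step of
#' `open_current_pA` from the first sample at which the pressure reaches
#' `threshold_mmHg`.
#'
#' @param threshold_mmHg True activation pressure (mmHg, suction magnitude).
#' @param ramp_rate_mmhg_s Ramp slope (mmHg/s).
#' @param open_current_pA Amplitude of the channel-opening current step (pA).
#' @param noise_sd_pA Standard deviation of the current noise (pA).
#' @param sampling_hz Sampling rate (Hz); patch-clamp recordings here are
#'   nominally 25 kHz.
#' @param max_pressure_mmHg End of the ramp; the threshold must be reachable.
#' @param seed Integer seed.
#'
#' @return A list with `recording` (tibble `time_s`, `pressure_mmhg`,
#'   `current_pa`, of class `pressure_recording` with a `sampling_hz`
#'   attribute) and `true_threshold_mmHg`.
#' @export
simulate_pressure_recording <- function(threshold_mmHg,
                                        ramp_rate_mmhg_s = 50,
                                        open_current_pA = 50,
                                        noise_sd_pA = 1,
                                        sampling_hz = 25000,
                                        max_pressure_mmHg = 200,
                                        seed = 1L) {
  stop_not_scalar(threshold_mmHg, "threshold_mmHg")
  if (sampling_hz <= 0) stop("`sampling_hz` must be > 0", call. = FALSE)
  if (ramp_rate_mmhg_s <= 0) stop("`ramp_rate_mmhg_s` must be > 0", call. = FALSE)
  if (threshold_mmHg > max_pressure_mmHg) {
    stop("threshold (", threshold_mmHg, " mmHg) is beyond the ramp end (",
      max_pressure_mmHg, " mmHg)",
      call. = FALSE
    )
  }
  set.seed(seed)
  n <- as.integer(ceiling(max_pressure_mmHg / ramp_rate_mmhg_s * sampling_hz)) + 1L
  time_s <- (seq_len(n) - 1L) / sampling_hz
  pressure <- ramp_rate_mmhg_s * time_s
  current <- rnorm(n, sd = noise_sd_pA)
  open <- pressure >= threshold_mmHg
  current[open] <- current[open] + open_current_pA
  rec <- tibble(time_s = time_s, pressure_mmhg = pressure, current_pa = current)
  attr(rec, "sampling_hz") <- sampling_hz
  class(rec) <- c("pressure_recording", class(rec))
  list(recording = rec, true_threshold_mmHg = threshold_mmHg)
}

#' Simulate a two-channel image pair with a target pixel correlation
#'
#' Pixel pairs are drawn from a bivariate normal distribution with
#' correlation `rho`; at `rho = 1` (or -1) the second channel is an exact
#' affine transform of the first.
#'
#' @param rho Target Pearson correlation in `[-1, 1]`.
#' @param n_pixels Approximate number of pixels; the images are square with
#'   side `round(sqrt(n_pixels))`.
#' @param seed Integer seed.
#' @param mean1,sd1,mean2,sd2 Marginal intensity moments of the two channels.
#'
#' @return A list with matrices `image1` and `image2` and the realized
#'   `n_pixels`.
#' @export
simulate_coloc_pair <- function(rho, n_pixels = 1e4, seed = 1L,
                                mean1 = 100, sd1 = 20, mean2 = 80, sd2 = 15) {
  stop_not_scalar(rho, "rho")
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  side <- max(2L, as.integer(round(sqrt(n_pixels))))
  n <- side^2
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(
    image1 = matrix(mean1 + sd1 * z1, side, side),
    image2 = matrix(mean2 + sd2 * z2, side, side),
    n_pixels = n
  )
}
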