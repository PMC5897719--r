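#' Event-detector parameters
#'
#' The detector accepts an onset when four conditions hold on the smoothed
#' dF/F0 trace: (i) the per-frame forward difference exceeds
#' `deriv_onset_threshold` throughout a right-interval of
#' `onset_check_frames` after the onset; the matching offset is the first
#' later time whose right-interval derivative stays below
#' `deriv_offset_threshold`; (ii) the dF between onset and the peak before
#' the offset exceeds the trace's noise threshold (standard deviation of
#' raw minus smoothed); and (iv) the gap between the last supra-threshold
#' derivative after the onset and the offset stays below
#' `max_rise_to_offset_frames`.
#'
#' @param mode `"asynchronous"` (onset threshold 1e-3 per frame) or
#'   `"synchronous"` (1e-2 per frame); the network-activity regime decides
#'   which derivative scale is meaningful.
#' @param deriv_onset_threshold Override for the onset derivative threshold
#'   (dF/F0 per frame, > 0).
#' @param deriv_offset_threshold Offset derivative threshold (< 0,
#'   default -1e-4).
#' @param max_rise_to_offset_frames Maximum allowed rise-end-to-offset gap in
#'   frames (default 300); set to `Inf` to disable the rule.
#' @param onset_check_frames Length of the right interval over which the
#'   derivative conditions must hold (default 10 frames, about 150 ms at
#'   65 Hz).
#'
#' @return An `event_params` list.
#' @export
event_params <- function(mode = c("asynchronous", "synchronous"),
                         deriv_onset_threshold = NULL,
                         deriv_offset_threshold = -1e-4,
                         max_rise_to_offset_frames = 300,
                         onset_check_frames = 10) {
  mode <- match.arg(mode)
  if (is.null(deriv_onset_threshold)) {
    deriv_onset_threshold <- if (mode == "asynchronous") 1e-3 else 1e-2
  }
  if (deriv_onset_threshold <= 0) {
    stop("`deriv_onset_threshold` must be > 0", call. = FALSE)
  }
  if (deriv_offset_threshold >= 0) {
    stop("`deriv_offset_threshold` must be < 0", call. = FALSE)
  }
  if (max_rise_to_offset_frames < 1) {
    stop("`max_rise_to_offset_frames` must be >= 1", call. = FALSE)
  }
  if (onset_check_frames < 1) {
    stop("`onset_check_frames` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      mode = mode,
      deriv_onset_threshold = deriv_onset_threshold,
      deriv_offset_threshold = deriv_offset_threshold,
      max_rise_to_offset_frames = max_rise_to_offset_frames,
      onset_check_frames = as.integer(onset_check_frames)
    ),
    class = "event_params"
  )
}

#' Detect calcium events on a single trace
#'
#' @param dff_smooth Smoothed dF/F0 trace (see [smooth_perona_malik()]).
#' @param dff_raw Raw dF/F0 trace of the same length; used only for the
#'   noise threshold of condition (ii).
#' @param params An [event_params()] object.
#'
#' @return Tibble with 0-based `onset_frame`, `offset_frame` and
#'   `amplitude_dff`, one row per accepted event; events are ordered and
#'   non-overlapping. A trace shorter than the checking windows yields an
#'   empty result with a warning.
#' @export
detect_events <- function(dff_smooth, dff_raw, params = event_params()) {
  stopifnot(inherits(params, "event_params"))
  if (length(dff_smooth) != length(dff_raw)) {
    stop("smoothed and raw traces must have the same length", call. = FALSE)
  }
  empty <- tibble(
    onset_frame = integer(0), offset_frame = integer(0),
    amplitude_dff = numeric(0)
  )
  w <- params$onset_check_frames
  n <- length(dff_smooth)
  if (n < w + 2L) {
    warning("trace shorter than the detector windows; no events detected")
    return(empty)
  }
  d <- diff(dff_smooth)
  resid <- dff_raw - dff_smooth
  noise_thr <- pop_sd(resid)
  ok_on <- runs_all(d > params$deriv_onset_threshold, w)
  ok_off <- runs_all(d < params$deriv_offset_threshold, w)
  onset_cand <- which(ok_on)
  offset_cand <- which(ok_off)
  if (!length(onset_cand) || !length(offset_cand)) {
    return(empty)
  }

  events <- list()
  resume <- 1L
  for (on in onset_cand) {
    if (on < resume) next
    off_pos <- offset_cand[offset_cand > on]
    if (!length(off_pos)) break
    off <- off_pos[1]
    seg <- d[on:off]
    last_rise <- on + max(which(seg > params$deriv_onset_threshold)) - 1L
    amp <- max(dff_smooth[on:off]) - dff_smooth[on]
    if ((off - last_rise) < params$max_rise_to_offset_frames &&
      amp > noise_thr) {
      events[[length(events) + 1L]] <-
        c(on = on - 1L, off = off - 1L, amp = amp) # 0-based
      resume <- off + 1L
    } else {
      resume <- on + 1L
    }
  }
  if (!length(events)) {
    return(empty)
  }
  m <- do.call(rbind, events)
  tibble(
    onset_frame = as.integer(m[, "on"]),
    offset_frame = as.integer(m[, "off"]),
    amplitude_dff = unname(m[, "amp"])
  )
}

#' Detect events for every ROI of a trace table
#'
#' @param traces A `ca_traces` tibble (see [normalize_traces()]) with
#'   `roi_id`, `frame`, `dff` and `dff_smooth` columns and a
#'   `frame_rate_hz` attribute.
#' @param params An [event_params()] object.
#' @param frame_rate_hz Acquisition rate; defaults to the table's attribute.
#'
#' @return A `network_activity` object: list with
#'   `events` (tibble `roi_id`, `onset_frame`, `onset_time_s`,
#'   `offset_frame`, `amplitude_dff`), `mfr` (tibble `roi_id`, `n_events`,
#'   `mfr_hz`), `duration_s` and `frame_rate_hz`.
#' @export
detect_events_all <- function(traces, params = event_params(),
                              frame_rate_hz = attr(traces, "frame_rate_hz")) {
  if (is.null(frame_rate_hz)) {
    stop("`frame_rate_hz` is neither given nor attached to `traces`", call. = FALSE)
  }
  if (!nrow(traces)) stop("`traces` contains no ROIs", call. = FALSE)
  duration_s <- max(tapply(traces$frame, traces$roi_id, length)) / frame_rate_hz
  events <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      detect_events(df$dff_smooth, df$dff, params)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(onset_time_s = .data$onset_frame / frame_rate_hz) |>
    dplyr::select(
      "roi_id", "onset_frame", "onset_time_s",
      "offset_frame", "amplitude_dff"
    )
  mfr <- tibble(roi_id = sort(unique(traces$roi_id))) |>
    dplyr::left_join(
      dplyr::count(events, .data$roi_id, name = "n_events"),
      by = "roi_id"
    ) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      mfr_hz = .data$n_events / duration_s
    )
  structure(
    list(
      events = events, mfr = mfr,
      duration_s = duration_s, frame_rate_hz = frame_rate_hz
    ),
    class = "network_activity"
  )
}

#' @export
print.network_activity <- function(x, ...) {
  cat(sprintf(
    "<network_activity> %d ROIs, %d events over %.1f s (mean MFR %.4g Hz)\n",
    nrow(x$mfr), nrow(x$events), x$duration_s, mean(x$mfr$mfr_hz)
  ))
  invisible(x)
}

#' Mean firing rate of an event train
#'
#' @param train Either an event tibble (one row per event) or a vector of
#'   onset frames.
#' @param duration_s Recording duration in seconds (> 0).
#'
#' @return Events per second.
#' @export
mean_firing_rate <- function(train, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  n <- if (is.data.frame(train)) nrow(train) else length(train)
  n / duration_s
}

#' Long-format raster of network activity
#'
#' @param activity A `network_activity` object.
#'
#' @return Tibble `(roi_id, onset_time_s)`, sorted by ROI then time.
#' @export
build_raster <- function(activity) {
  stopifnot(inherits(activity, "network_activity"))
  activity$events |>
    dplyr::select("roi_id", "onset_time_s") |>
    dplyr::arrange(.data$roi_id, .data$onset_time_s)
}

#' @rdname detect_events_all
#' @param x A `network_activity` object.
#' @param ... Unused.
#' @method tidy network_activity
#' @export
tidy.network_activity <- function(x, ...) {
  x$events
}

#' @rdname detect_events_all
#' @method glance network_activity
#' @export
glance.network_activity <- function(x, ...) {
  tibble(
    n_rois = nrow(x$mfr),
    n_events = nrow(x$events),
    duration_s = x$duration_s,
    mean_mfr_hz = mean(x$mfr$mfr_hz),
    sem_mfr_hz = if (nrow(x$mfr) > 1) sd(x$mfr$mfr_hz) / sqrt(nrow(x$mfr)) else 0
  )
}

#' Match detected onsets to ground-truth onsets
#'
#' Greedy one-to-one matching within a frame tolerance, used to score the
#' detector against simulated ground truth.
#'
#' @param detected,truth Vectors of onset frames (any common 0- or 1-based
#'   convention, as long as it is shared).
#' @param tol_frames Matching tolerance in frames (default 5).
#'
#' @return Tibble with `n_detected`, `n_true`, `n_matched`, `recall`
#'   (matched / true) and `precision` (matched / detected).
#' @export
match_events <- function(detected, truth, tol_frames = 5) {
  detected <- sort(detected)
  truth <- sort(truth)
  used <- logical(length(detected))
  n_matched <- 0L
  for (t in truth) {
    cand <- which(!used & abs(detected - t) <= tol_frames)
    if (length(cand)) {
      used[cand[which.min(abs(detected[cand] - t))]] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  tibble(
    n_detected = length(detected), n_true = length(truth),
    n_matched = n_matched,
    recall = if (length(truth)) n_matched / length(truth) else NA_real_,
    precision = if (length(detected)) n_matched / length(detected) else NA_real_
  )
}
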