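# file I/O: multi-page TIFF movies, ROI/trace/event CSVs, ground-truth JSON

#' Write and read movies as multi-page TIFF
#'
#' Movies are stored as single-channel 16-bit unsigned multi-page TIFF with
#' page order equal to time. Intensities are scaled by `scale` into the
#' 16-bit range on write and unscaled on read, so a round trip recovers the
#' input up to 1/65535 quantization.
#'
#' @param movie A [ca_movie()].
#' @param path Output file.
#' @param scale Intensity corresponding to the full 16-bit range; defaults to
#'   the movie's maximum.
#'
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie$frames)) {
  stopifnot(inherits(movie, "ca_movie"))
  if (scale <= 0) scale <- 1
  n_frames <- dim(movie$frames)[3]
  pages <- lapply(seq_len(n_frames), function(t) {
    pmin(pmax(movie$frames[, , t] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate_hz Frame rate to attach on read (Hz).
#' @export
read_movie_tiff <- function(path, frame_rate_hz, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(
    unlist(pages),
    dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages))
  )
  ca_movie(frames * scale, frame_rate_hz)
}

#' Write simulation ground truth as JSON
#'
#' Cell centers are 0-based (row, col) pixel coordinates and onsets 0-based
#' frame indices, matching all other outputs of the package.
#'
#' @param truth Ground-truth tibble from [simulate_movie()].
#' @param path Output file.
#'
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      cell_centers = truth[, c("row", "col")],
      event_onsets = truth$onsets,
      true_mfr = truth$true_mfr_hz
    ),
    path,
    digits = NA
  )
  invisible(path)
}

#' Write a ROI set as a 16-bit label-map TIFF plus a CSV table
#'
#' Produces `<stem>_labels.tif` (pixel value = ROI label, 0 = background)
#' and `<stem>_rois.csv` with columns
#' `roi_id,area_px,centroid_row,centroid_col` (0-based centroids).
#'
#' @param rois A `roi_set`.
#' @param stem Output path stem.
#'
#' @return Character vector of the two paths, invisibly.
#' @export
write_roi_set <- function(rois, stem) {
  stopifnot(inherits(rois, "roi_set"))
  paths <- paste0(stem, c("_labels.tif", "_rois.csv"))
  tiff::writeTIFF(rois$label_map / 65535, paths[1], bits.per.sample = 16L)
  readr::write_csv(tidy(rois), paths[2])
  invisible(paths)
}

#' Pressure-recording CSV I/O
#'
#' CSV schema: header `time_s,pressure_mmhg,current_pa`, one row per sample.
#'
#' @param rec Recording tibble.
#' @param path File path.
#'
#' @return The recording tibble (invisibly for the writer).
#' @export
write_pressure_csv <- function(rec, path) {
  readr::write_csv(rec[, c("time_s", "pressure_mmhg", "current_pa")], path)
  invisible(rec)
}

#' @rdname write_pressure_csv
#' @export
read_pressure_csv <- function(path) {
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      time_s = readr::col_double(),
      pressure_mmhg = readr::col_double(),
      current_pa = readr::col_double()
    )
  )
  class(rec) <- c("pressure_recording", class(rec))
  rec
}

#' Trace-table CSV I/O
#'
#' Traces are written wide (one column per ROI named `roi_<id>`, one row per
#' frame) to match the conventional layout of imaging toolchains, and read
#' back into the package's long format.
#'
#' @param traces Long trace tibble with `roi_id`, `frame` and `f_raw`.
#' @param path File path.
#'
#' @return For the reader, a long tibble `roi_id`, `frame`, `time_s`,
#'   `f_raw` with the `frame_rate_hz` attribute set.
#' @export
write_traces_csv <- function(traces, path) {
  wide <- traces |>
    dplyr::select("roi_id", "frame", "f_raw") |>
    dplyr::mutate(roi_id = sprintf("roi_%d", .data$roi_id)) |>
    tidyr::pivot_wider(names_from = "roi_id", values_from = "f_raw") |>
    dplyr::arrange(.data$frame)
  readr::write_csv(wide, path)
  invisible(traces)
}

#' @rdname write_traces_csv
#' @param frame_rate_hz Frame rate to attach on read (Hz).
#' @export
read_traces_csv <- function(path, frame_rate_hz) {
  wide <- readr::read_csv(path, col_types = readr::cols())
  out <- wide |>
    tidyr::pivot_longer(-"frame", names_to = "roi_id", values_to = "f_raw") |>
    dplyr::mutate(
      roi_id = as.integer(sub("^roi_", "", .data$roi_id)),
      time_s = .data$frame / frame_rate_hz
    ) |>
    dplyr::arrange(.data$roi_id, .data$frame) |>
    dplyr::select("roi_id", "frame", "time_s", "f_raw")
  attr(out, "frame_rate_hz") <- frame_rate_hz
  out
}

#' Write detected events and firing rates as CSV
#'
#' Two files are produced: `<stem>_events.csv` with columns
#' `roi_id,onset_frame,onset_time_s,offset_frame,amplitude_dff` and
#' `<stem>_mfr.csv` with `roi_id,n_events,mfr_hz`.
#'
#' @param activity A `network_activity` object.
#' @param stem Output path stem.
#'
#' @return Character vector of the two paths, invisibly.
#' @export
write_events_csv <- function(activity, stem) {
  stopifnot(inherits(activity, "network_activity"))
  paths <- paste0(stem, c("_events.csv", "_mfr.csv"))
  readr::write_csv(activity$events, paths[1])
  readr::write_csv(activity$mfr, paths[2])
  invisible(paths)
}
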