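#' Temporal standard-deviation projection of a movie
#'
#' Computes, for each pixel, the standard deviation of its intensity over
#' time (population convention, divide by the number of frames). Active cells
#' appear bright while static background — however non-uniform — projects to
#' the noise floor.
#'
#' @param movie A [ca_movie()].
#'
#' @return A `height x width` numeric matrix.
#' @export
std_projection <- function(movie) {
  stopifnot(inherits(movie, "ca_movie"))
  n_frames <- dim(movie$frames)[3]
  if (n_frames < 2L) stop("std projection needs at least 2 frames", call. = FALSE)
  m1 <- rowMeans(movie$frames, dims = 2)
  m2 <- rowMeans(movie$frames^2, dims = 2)
  sqrt(pmax(m2 - m1^2, 0))
}

# offsets (drow, dcol) of a Euclidean disk of the given radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(drow = -r:r, dcol = -r:r)
  g[g$drow^2 + g$dcol^2 <= radius^2, , drop = FALSE]
}

# sliding min (erode) or max (dilate) over a structuring element; outside
# pixels are ignored (the element is clipped at the image border)
morph_filter <- function(image, offsets, op = c("min", "max")) {
  op <- match.arg(op)
  h <- nrow(image)
  w <- ncol(image)
  pad <- if (op == "min") Inf else -Inf
  out <- matrix(pad, h, w)
  cmp <- if (op == "min") pmin else pmax
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets$drow[k]
    dc <- offsets$dcol[k]
    rows_out <- max(1, 1 - dr):min(h, h - dr)
    cols_out <- max(1, 1 - dc):min(w, w - dc)
    out[rows_out, cols_out] <- cmp(
      out[rows_out, cols_out],
      image[rows_out + dr, cols_out + dc]
    )
  }
  out
}

#' Estimate a smooth background by grayscale morphological opening
#'
#' Erosion followed by dilation with a Euclidean disk. Bright features
#' smaller than the disk are removed, leaving the smooth background; the
#' result never exceeds the input. The disk should be smaller than the
#' typical soma so that cells are treated as foreground.
#'
#' @param image Numeric matrix (e.g. a [std_projection()]).
#' @param disk_radius_px Disk radius in pixels (>= 1 and smaller than the
#'   image).
#'
#' @return Matrix of the same size, pixelwise `<=` the input.
#' @export
estimate_background <- function(image, disk_radius_px = 5) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (disk_radius_px < 1) stop("`disk_radius_px` must be >= 1", call. = FALSE)
  if (2 * disk_radius_px + 1 > min(dim(image))) {
    stop("structuring element larger than the image", call. = FALSE)
  }
  se <- disk_offsets(disk_radius_px)
  morph_filter(morph_filter(image, se, "min"), se, "max")
}

#' Subtract an estimated background, clamping at zero
#'
#' @param image,background Numeric matrices of identical size.
#'
#' @return `pmax(image - background, 0)`.
#' @export
subtract_background <- function(image, background) {
  if (!identical(dim(image), dim(background))) {
    stop("`image` and `background` must have the same shape", call. = FALSE)
  }
  pmax(image - background, 0)
}

# 8-connected component labelling of a logical mask; labels are assigned in
# raster-scan order (row-major, 0-based convention of the outputs) of each
# component's first pixel
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  # raster order = row-major
  order_idx <- as.vector(t(matrix(seq_len(h * w), h, w)))
  fg <- order_idx[mask[order_idx]]
  next_label <- 0L
  for (start in fg) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- ((cur - 1L) %% h) + 1L
      c <- ((cur - 1L) %/% h) + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          rr <- r + dr
          cc <- c + dc
          ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
          nb <- (cc[ok] - 1L) * h + rr[ok]
          nb <- nb[mask[nb] & labels[nb] == 0L]
          if (length(nb)) {
            labels[nb] <- next_label
            queue <- c(queue, nb)
          }
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

#' Detect cell ROIs in a projection image
#'
#' Binarizes the image with Otsu's threshold (unless an explicit threshold is
#' given), labels 8-connected foreground components, discards components
#' smaller than `min_area_px`, and re-indexes the surviving ROIs from 1 in
#' raster-scan order of their first pixel. A constant image yields an empty
#' ROI set rather than an error.
#'
#' @param image Nonnegative numeric matrix, typically a background-subtracted
#'   [std_projection()].
#' @param min_area_px Minimum ROI area in pixels; a sensible choice is the
#'   area of a disk of half the expected soma radius.
#' @param threshold Optional binarization threshold overriding Otsu.
#'
#' @return A `roi_set`: list with `label_map` (integer matrix, 0 background),
#'   `roi_ids`, `areas`, and a `centroids` tibble (0-based row/col).
#' @export
detect_rois <- function(image, min_area_px = 5, threshold = NULL) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(image < 0)) stop("`image` must be nonnegative", call. = FALSE)
  rng <- range(image)
  if (is.null(threshold)) {
    if (rng[1] == rng[2]) {
      return(new_roi_set(matrix(0L, nrow(image), ncol(image))))
    }
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(scaled, range = c(0, 1)) * (rng[2] - rng[1])
  }
  mask <- image > threshold
  labels <- label_components(mask)
  if (max(labels) > 0L) {
    areas <- tabulate(labels, nbins = max(labels))
    keep <- which(areas >= min_area_px)
    relabel <- integer(max(labels))
    relabel[keep] <- seq_along(keep)
    labels[labels > 0L] <- relabel[labels[labels > 0L]]
  }
  new_roi_set(labels)
}

new_roi_set <- function(label_map) {
  ids <- seq_len(max(label_map, 0L))
  areas <- if (length(ids)) tabulate(label_map, nbins = max(ids)) else integer(0)
  centroids <- purrr::map_dfr(ids, function(k) {
    idx <- which(label_map == k, arr.ind = TRUE)
    tibble(
      roi_id = k, area_px = nrow(idx),
      centroid_row = mean(idx[, 1]) - 1, centroid_col = mean(idx[, 2]) - 1
    )
  })
  structure(
    list(
      label_map = label_map, roi_ids = ids,
      areas = areas, centroids = centroids
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "<roi_set> %d ROIs on a %d x %d label map\n",
    length(x$roi_ids), nrow(x$label_map), ncol(x$label_map)
  ))
  invisible(x)
}

#' @rdname detect_rois
#' @param x A `roi_set`.
#' @param ... Unused.
#' @method tidy roi_set
#' @export
tidy.roi_set <- function(x, ...) {
  if (length(x$roi_ids) == 0L) {
    return(tibble(
      roi_id = integer(0), area_px = integer(0),
      centroid_row = numeric(0), centroid_col = numeric(0)
    ))
  }
  x$centroids
}

#' Run the full segmentation chain on a movie
#'
#' [std_projection()], then [estimate_background()] and
#' [subtract_background()], then [detect_rois()].
#'
#' @inheritParams std_projection
#' @inheritParams estimate_background
#' @inheritParams detect_rois
#'
#' @return A `roi_set`.
#' @export
segment_movie <- function(movie, disk_radius_px = 5, min_area_px = 5,
                          threshold = NULL) {
  proj <- std_projection(movie)
  bg <- estimate_background(proj, disk_radius_px)
  detect_rois(subtract_background(proj, bg), min_area_px, threshold)
}

#' Map ground-truth cell centers to detected ROI labels
#'
#' Looks up each (0-based) cell center in the ROI label map, giving the
#' correspondence needed to score segmentation and event detection against
#' simulated ground truth.
#'
#' @param rois A `roi_set`.
#' @param truth Ground-truth tibble from [simulate_movie()].
#'
#' @return The truth tibble with a `roi_id` column added (`NA` when the
#'   center lies on background).
#' @export
match_rois_to_cells <- function(rois, truth) {
  stopifnot(inherits(rois, "roi_set"))
  ids <- rois$label_map[cbind(round(truth$row) + 1L, round(truth$col) + 1L)]
  dplyr::mutate(truth, roi_id = ifelse(ids == 0L, NA_integer_, ids))
}

#' Extract mean-ROI fluorescence traces
#'
#' For each ROI, the trace value at a frame is the mean intensity over the
#' ROI's pixels in that frame.
#'
#' @param movie A [ca_movie()].
#' @param rois A `roi_set` whose label map matches the movie's frame size.
#'
#' @return A tibble in long format with columns `roi_id`, `frame` (0-based),
#'   `time_s`, and `f_raw`; the frame rate is carried in the `frame_rate_hz`
#'   attribute. An empty ROI set yields an empty tibble.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"), inherits(rois, "roi_set"))
  d <- dim(movie$frames)
  if (!identical(dim(rois$label_map), d[1:2])) {
    stop("label map does not match the movie's frame size", call. = FALSE)
  }
  n_frames <- d[3]
  flat <- movie$frames
  dim(flat) <- c(d[1] * d[2], n_frames)
  out <- purrr::map_dfr(rois$roi_ids, function(k) {
    idx <- which(rois$label_map == k)
    tibble(
      roi_id = k,
      frame = seq_len(n_frames) - 1L,
      time_s = (seq_len(n_frames) - 1L) / movie$frame_rate_hz,
      f_raw = colMeans(flat[idx, , drop = FALSE])
    )
  })
  if (nrow(out) == 0L) {
    out <- tibble(
      roi_id = integer(0), frame = integer(0),
      time_s = numeric(0), f_raw = numeric(0)
    )
  }
  attr(out, "frame_rate_hz") <- movie$frame_rate_hz
  out
}
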