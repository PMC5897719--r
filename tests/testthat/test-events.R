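test_that("event parameter validation and mode thresholds", {
  expect_equal(event_params("asynchronous")$deriv_onset_threshold, 1e-3)
  expect_equal(event_params("synchronous")$deriv_onset_threshold, 1e-2)
  expect_error(event_params(deriv_onset_threshold = -1), "onset")
  expect_error(event_params(deriv_offset_threshold = 0.1), "offset")
  expect_error(event_params(onset_check_frames = 0), "onset_check_frames")
})

test_that("a flat or sub-threshold-noise trace yields no events", {
  flat <- rep(0, 1000)
  expect_equal(nrow(detect_events(flat, flat)), 0L)
  set.seed(2)
  noisy <- rnorm(2000, sd = 0.005)
  sm <- smooth_perona_malik(noisy)
  expect_equal(nrow(detect_events(sm, noisy)), 0L)
})

test_that("a single clean transient is detected once, at the right onset, by the stated conditions", {
  tr <- transient_trace(n = 2000, onsets = 500, rise = 10, amp = 0.1, seed = 1)
  sm <- smooth_perona_malik(tr$dff)
  ev <- detect_events(sm, tr$dff)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$onset_frame + 1 - 500), 3) # 0-based vs 1-based

  # direct evaluation of each condition at the detected event
  d <- diff(sm)
  on <- ev$onset_frame + 1
  off <- ev$offset_frame + 1
  w <- event_params()$onset_check_frames
  expect_true(all(d[on:(on + w - 1)] > 1e-3)) # (i) rising right-interval
  expect_true(all(d[off:(off + w - 1)] < -1e-4)) # (iii) falling right-interval
  noise_thr <- camech:::pop_sd(tr$dff - sm)
  expect_gt(ev$amplitude_dff, noise_thr) # (ii) amplitude above noise
  last_rise <- max(which(d[on:off] > 1e-3)) + on - 1
  expect_lt(off - last_rise, 300) # (iv) rise-to-offset gap
  expect_equal(ev$amplitude_dff, max(sm[on:off]) - sm[on])
})

test_that("an amplitude well below the noise threshold is rejected by condition (ii)", {
  base <- transient_trace(n = 2000, onsets = numeric(0), noise_sd = 0.005, seed = 3)
  sm0 <- smooth_perona_malik(base$dff)
  noise_thr <- camech:::pop_sd(base$dff - sm0)
  small <- transient_trace(
    n = 2000, onsets = 500, rise = 10,
    amp = 0.2 * noise_thr, noise_sd = 0.005, seed = 3
  )
  sm <- smooth_perona_malik(small$dff)
  expect_equal(nrow(detect_events(sm, small$dff)), 0L)
})

test_that("two transients five seconds apart give two ordered events", {
  tr <- transient_trace(n = 2000, onsets = c(400, 400 + 5 * 65), seed = 4)
  sm <- smooth_perona_malik(tr$dff)
  ev <- detect_events(sm, tr$dff)
  expect_equal(nrow(ev), 2L)
  expect_true(all(diff(ev$onset_frame) > 0))
  expect_true(all(ev$onset_frame < ev$offset_frame))
})

test_that("detection is monotone in amplitude and in the mode threshold", {
  amps <- c(0.05, 0.1, 0.2, 0.4)
  detected <- vapply(amps, function(a) {
    tr <- transient_trace(n = 2000, onsets = 500, amp = a, seed = 5)
    sm <- smooth_perona_malik(tr$dff)
    nrow(detect_events(sm, tr$dff))
  }, numeric(1))
  expect_true(all(diff(detected) >= 0)) # scaling up never loses the event

  # synchronous mode (10x onset threshold) can only remove events
  set.seed(6)
  for (i in 1:5) {
    tr <- transient_trace(
      n = 3000, onsets = sort(sample(200:2500, 4)),
      amp = runif(1, 0.05, 0.3), noise_sd = 0.01, seed = i
    )
    sm <- smooth_perona_malik(tr$dff)
    n_async <- nrow(detect_events(sm, tr$dff, event_params("asynchronous")))
    n_sync <- nrow(detect_events(sm, tr$dff, event_params("synchronous")))
    expect_lte(n_sync, n_async)
  }
})

test_that("detector is deterministic and errors on malformed input", {
  tr <- transient_trace(seed = 8)
  sm <- smooth_perona_malik(tr$dff)
  expect_identical(detect_events(sm, tr$dff), detect_events(sm, tr$dff))
  expect_error(detect_events(sm, tr$dff[-1]), "same length")
  expect_warning(detect_events(rep(0, 5), rep(0, 5)), "shorter")
})

test_that("per-network detection fills MFR, raster and summaries consistently", {
  fps <- 65
  tr_active <- transient_trace(n = 3000, onsets = c(500, 1500), seed = 9)
  flat <- rep(0, 3000)
  traces <- dplyr::bind_rows(
    tibble::tibble(
      roi_id = 1L, frame = 0:2999,
      dff = tr_active$dff, dff_smooth = smooth_perona_malik(tr_active$dff)
    ),
    tibble::tibble(roi_id = 2L, frame = 0:2999, dff = flat, dff_smooth = flat)
  )
  act <- detect_events_all(traces, frame_rate_hz = fps)
  expect_equal(act$mfr$n_events, c(2L, 0L))
  expect_equal(sum(act$mfr$mfr_hz > 0), 1)
  expect_equal(act$duration_s, 3000 / fps)

  raster <- build_raster(act)
  expect_equal(nrow(raster), sum(act$mfr$n_events)) # conservation
  expect_equal(
    sum(act$mfr$mfr_hz * act$duration_s), nrow(raster),
    tolerance = 1e-9
  )
  expect_equal(tidy(act), act$events)
  g <- glance(act)
  expect_equal(g$n_events, 2L)
  expect_equal(g$n_rois, 2L)

  # all-flat network
  allflat <- tibble::tibble(
    roi_id = rep(1:2, each = 100), frame = rep(0:99, 2),
    dff = 0, dff_smooth = 0
  )
  act0 <- detect_events_all(allflat, frame_rate_hz = fps)
  expect_true(all(act0$mfr$mfr_hz == 0))
  expect_equal(nrow(build_raster(act0)), 0L)
})

test_that("mean firing rate is events per second", {
  expect_equal(mean_firing_rate(integer(0), 60), 0)
  expect_equal(mean_firing_rate(seq_len(12), 60), 0.2)
  expect_equal(mean_firing_rate(tibble::tibble(onset_frame = 1:3), 10), 0.3)
  expect_error(mean_firing_rate(1:3, 0), "duration_s")
})

test_that("raster converts onset frames to seconds", {
  traces <- tibble::tibble(
    roi_id = 1L, frame = 0:199,
    dff = 0, dff_smooth = 0
  )
  act <- detect_events_all(traces, frame_rate_hz = 65)
  act$events <- tibble::tibble(
    roi_id = 1L, onset_frame = c(65L, 130L),
    onset_time_s = c(65, 130) / 65, offset_frame = c(100L, 160L),
    amplitude_dff = c(0.1, 0.2)
  )
  expect_equal(build_raster(act)$onset_time_s, c(1, 2))
})

test_that("event matching scores recall and precision with one-to-one pairing", {
  m <- match_events(c(10, 50, 90), c(11, 52, 300), tol_frames = 5)
  expect_equal(m$n_matched, 2L)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 2 / 3)
  # a single detection cannot match two truths
  m2 <- match_events(50, c(48, 52), tol_frames = 5)
  expect_equal(m2$n_matched, 1L)
})
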