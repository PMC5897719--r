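test_that("a field without cells, noise or gradient is constant at the baseline", {
  p <- movie_sim_params(
    n_cells = 0, height = 8, width = 8, duration_s = 1,
    noise_sd = 0, background_gradient = 0, baseline_level = 10, seed = 1
  )
  sim <- simulate_movie(p)
  expect_true(all(sim$movie$frames == 10))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("zero event rate yields empty onset lists and zero MFR", {
  p <- movie_sim_params(
    n_cells = 5, height = 48, width = 48, duration_s = 2,
    event_rate_hz = 0, seed = 3
  )
  sim <- simulate_movie(p)
  expect_identical(nrow(sim$truth), 5L)
  expect_true(all(lengths(sim$truth$onsets) == 0))
  expect_true(all(sim$truth$true_mfr_hz == 0))
})

test_that("invalid movie parameters are rejected", {
  expect_error(movie_sim_params(duration_s = 0), "duration_s")
  expect_error(movie_sim_params(frame_rate_hz = -1), "frame_rate_hz")
  expect_error(movie_sim_params(noise_sd = -0.1), "noise_sd")
  expect_error(movie_sim_params(n_cells = -1), "n_cells")
})

test_that("simulation is bit-reproducible given the seed and varies across seeds", {
  p1 <- movie_sim_params(n_cells = 1, height = 16, width = 16, duration_s = 2, seed = 7)
  a <- simulate_movie(p1)
  b <- simulate_movie(p1)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth$onsets, b$truth$onsets)
  p2 <- movie_sim_params(n_cells = 1, height = 16, width = 16, duration_s = 2, seed = 8)
  d <- simulate_movie(p2)
  expect_false(identical(a$movie$frames, d$movie$frames))
})

test_that("seeded event counts match the Poisson mean within 3 standard errors", {
  # 30 independent single-cell movies, rate 2 Hz for 10 s: total mean 600
  total <- sum(vapply(1:30, function(s) {
    sim <- simulate_movie(movie_sim_params(
      n_cells = 1, height = 16, width = 16, duration_s = 10,
      event_rate_hz = 2, seed = s
    ))
    sum(sim$truth$n_events)
  }, numeric(1)))
  expect_lt(abs(total - 600), 3 * sqrt(600))
  # onsets are sorted and within range
  sim <- simulate_movie(movie_sim_params(
    n_cells = 3, height = 48, width = 48, duration_s = 20,
    event_rate_hz = 0.5, seed = 5
  ))
  for (o in sim$truth$onsets) {
    expect_true(all(diff(o) > 0))
    expect_true(all(o >= 0 & o < 20 * 65))
  }
})

test_that("noise-free single-cell movie reproduces the programmed waveform up to an affine scale", {
  p <- movie_sim_params(
    n_cells = 1, height = 32, width = 32, duration_s = 10,
    noise_sd = 0, background_gradient = 0, event_rate_hz = 0.3, seed = 4
  )
  sim <- simulate_movie(p)
  # ROI = 2-sigma disk around the true center
  ctr <- c(sim$truth$row[1], sim$truth$col[1]) + 1
  d2 <- outer((seq_len(32) - ctr[1])^2, (seq_len(32) - ctr[2])^2, `+`)
  mask <- d2 <= p$cell_radius_px^2
  label <- matrix(0L, 32, 32)
  label[mask] <- 1L
  flat <- sim$movie$frames
  dim(flat) <- c(32 * 32, dim(sim$movie$frames)[3])
  trace <- colMeans(flat[which(mask), ])
  # programmed dF/F0 of the cell
  kernel_len <- p$rise_frames + ceiling(6 * p$decay_tau_s * p$frame_rate_hz)
  dff <- numeric(length(trace))
  k <- c(
    p$amplitude_dff * seq_len(p$rise_frames) / p$rise_frames,
    p$amplitude_dff * exp(-seq_len(kernel_len - p$rise_frames) /
      (p$decay_tau_s * p$frame_rate_hz))
  )
  for (o in sim$truth$onsets[[1]]) {
    idx <- (o + 1):min(length(dff), o + kernel_len)
    dff[idx] <- dff[idx] + k[seq_along(idx)]
  }
  expect_gt(length(sim$truth$onsets[[1]]), 0)
  fit <- lm(trace ~ dff)
  resid_rel <- max(abs(residuals(fit))) / (max(trace) - min(trace))
  expect_lt(resid_rel, 0.01)
})

test_that("pressure recording has an exact current step when noise-free", {
  s <- simulate_pressure_recording(
    threshold_mmHg = 70, noise_sd_pA = 0,
    open_current_pA = 50, sampling_hz = 5000, seed = 1
  )
  rec <- s$recording
  pre <- rec$current_pa[rec$pressure_mmhg < 70]
  post <- rec$current_pa[rec$pressure_mmhg >= 70]
  expect_true(all(pre == 0))
  expect_true(all(post == 50))
  expect_equal(s$true_threshold_mmHg, 70)
})

test_that("a threshold beyond the ramp end is an error", {
  expect_error(
    simulate_pressure_recording(threshold_mmHg = 150, max_pressure_mmHg = 100),
    "beyond the ramp end"
  )
})

test_that("coloc pair hits the target correlation", {
  perfect <- simulate_coloc_pair(1, n_pixels = 400, seed = 2)
  expect_equal(
    pearson_colocalization(perfect$image1, perfect$image2), 1,
    tolerance = 1e-12
  )
  null <- simulate_coloc_pair(0, n_pixels = 1e4, seed = 3)
  expect_lt(abs(pearson_colocalization(null$image1, null$image2)), 0.05)
  expect_error(simulate_coloc_pair(1.2), "rho")
})

test_that("movies and recordings round-trip through their file formats", {
  p <- movie_sim_params(
    n_cells = 1, height = 16, width = 16, duration_s = 1,
    seed = 9, baseline_level = 50
  )
  sim <- simulate_movie(p)
  tf <- withr::local_tempfile(fileext = ".tif")
  scale <- max(sim$movie$frames)
  write_movie_tiff(sim$movie, tf, scale = scale)
  back <- read_movie_tiff(tf, frame_rate_hz = 65, scale = scale)
  expect_equal(dim(back$frames), dim(sim$movie$frames))
  expect_lt(max(abs(back$frames - sim$movie$frames)), scale / 65535 + 1e-9)

  s <- simulate_pressure_recording(70, sampling_hz = 1000, seed = 1)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_pressure_csv(s$recording, cf)
  rec2 <- read_pressure_csv(cf)
  expect_equal(rec2$current_pa, s$recording$current_pa, tolerance = 1e-9)

  jf <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(sim$truth, jf)
  gt <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(unlist(gt$true_mfr), sim$truth$true_mfr_hz)

  rois <- segment_movie(simulate_movie(movie_sim_params(
    n_cells = 2, height = 48, width = 48, duration_s = 20,
    event_rate_hz = 0.5, seed = 12
  ))$movie)
  stem <- withr::local_tempfile()
  paths <- write_roi_set(rois, stem)
  labels <- round(tiff::readTIFF(paths[1]) * 65535)
  expect_equal(max(labels), length(rois$roi_ids))
  tab <- readr::read_csv(paths[2], col_types = readr::cols())
  expect_equal(tab$roi_id, rois$roi_ids)
})
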