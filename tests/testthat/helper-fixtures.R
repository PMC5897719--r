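# fixtures are built in code; nothing is stored on disk

# dF/F0 trace with transients at known onsets (1-based onset frames)
transient_trace <- function(n = 2000, onsets = 500, rise = 10, amp = 0.1,
                            tau_s = 1, fps = 65, noise_sd = 0.005, seed = 1) {
  set.seed(seed)
  decay <- ceiling(6 * tau_s * fps)
  kernel <- c(
    amp * seq_len(rise) / rise,
    amp * exp(-seq_len(decay) / (tau_s * fps))
  )
  clean <- numeric(n)
  for (o in onsets) {
    idx <- o:min(n, o + length(kernel) - 1L)
    clean[idx] <- clean[idx] + kernel[seq_along(idx)]
  }
  list(
    dff = clean + rnorm(n, sd = noise_sd),
    clean = clean,
    onsets = onsets
  )
}

# brute-force grayscale opening with a Euclidean disk: per-pixel min over
# the clipped disk, then per-pixel max; independent of the package's
# shifted-matrix implementation
brute_opening <- function(image, radius) {
  h <- nrow(image)
  w <- ncol(image)
  r <- floor(radius)
  pass <- function(img, fun) {
    out <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        vals <- c()
        for (di in -r:r) {
          for (dj in -r:r) {
            if (di^2 + dj^2 > radius^2) next
            ii <- i + di
            jj <- j + dj
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
              vals <- c(vals, img[ii, jj])
            }
          }
        }
        out[i, j] <- fun(vals)
      }
    }
    out
  }
  pass(pass(image, min), max)
}

# exhaustive two-sided Mann-Whitney p-value by permutation enumeration
# (tie-free samples only)
brute_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, `>`))
  }
  u_obs <- sum(outer(a, b, `>`))
  mn <- n_a * length(b)
  dev_obs <- abs(u_obs - mn / 2)
  all_idx <- utils::combn(length(pooled), n_a)
  u_all <- apply(all_idx, 2, u_stat)
  mean(abs(u_all - mn / 2) >= dev_obs - 1e-12)
}

# small movie fixture shared by segmentation tests
small_active_movie <- function(n_cells = 5, duration_s = 60, seed = 2,
                               event_rate_hz = 0.2) {
  simulate_movie(movie_sim_params(
    n_cells = n_cells, height = 48, width = 48,
    duration_s = duration_s, event_rate_hz = event_rate_hz, seed = seed
  ))
}
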