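# Pa per mmHg (conventional definition)
MMHG_TO_PA <- 133.322387415

#' Convert a pressure from mmHg to pascal
#'
#' Suction pressures are stored as positive magnitudes in mmHg throughout the
#' package (the physical stimulus is a negative pressure of that magnitude).
#'
#' @param p Pressure in mmHg.
#'
#' @return Pressure in Pa (`p * 133.322`).
#' @export
#' @examples
#' mmhg_to_pa(145) / 1e6 # ~0.02 MPa
mmhg_to_pa <- function(p) {
  p * MMHG_TO_PA
}

#' Laplace-law estimate of the membrane tension in a pipette patch
#'
#' For a membrane dome aspirated into a pipette of tip radius `r` under
#' suction `P`, the bilayer tension is `tau = gamma + r * P / 2`, where
#' `gamma` is the membrane-glass adhesion energy. Unit chain:
#' `tau[mN/m] = gamma[mN/m] + (r[m] * P[Pa] / 2) * 1e3`.
#'
#' @param pressure_mmHg Suction magnitude in mmHg (>= 0).
#' @param radius_um Pipette tip radius in micrometres (> 0, default 1).
#' @param gamma_mN_per_m Adhesion energy in mN/m (>= 0). Literature values:
#'   3.7 for a homogeneous phospholipid membrane, 1.6 for a neuronal
#'   membrane.
#'
#' @return Tension in mN/m. Vectorized over all arguments.
#' @export
#' @examples
#' membrane_tension(150, 1, 3.7) # ~13.7 mN/m
membrane_tension <- function(pressure_mmHg, radius_um = 1, gamma_mN_per_m) {
  if (any(pressure_mmHg < 0)) stop("`pressure_mmHg` must be >= 0 (suction magnitude)", call. = FALSE)
  if (any(radius_um <= 0)) stop("`radius_um` must be > 0", call. = FALSE)
  if (any(gamma_mN_per_m < 0)) stop("`gamma_mN_per_m` must be >= 0", call. = FALSE)
  r_m <- radius_um * 1e-6
  p_pa <- mmhg_to_pa(pressure_mmHg)
  gamma_mN_per_m + (r_m * p_pa / 2) * 1e3
}

#' Tension range over a set of adhesion energies
#'
#' Evaluates [membrane_tension()] at the smallest and largest adhesion energy
#' considered plausible for the preparation, bracketing the true tension.
#'
#' @inheritParams membrane_tension
#' @param gammas Adhesion energies in mN/m (default `c(1.6, 3.7)`).
#' @param report If `TRUE`, apply the one-decimal reporting rule
#'   (round to two decimals, then truncate to one) to the bounds.
#'
#' @return Tibble with `pressure_mmHg`, `tension_low`, `tension_high` (mN/m).
#' @export
#' @examples
#' tension_range(150, report = TRUE) # 11.6 - 13.7 mN/m
tension_range <- function(pressure_mmHg, radius_um = 1,
                          gammas = c(1.6, 3.7), report = FALSE) {
  if (!length(gammas)) stop("`gammas` must be non-empty", call. = FALSE)
  lo <- membrane_tension(pressure_mmHg, radius_um, min(gammas))
  hi <- membrane_tension(pressure_mmHg, radius_um, max(gammas))
  if (report) {
    lo <- report_one_decimal(lo)
    hi <- report_one_decimal(hi)
  }
  tibble(
    pressure_mmHg = pressure_mmHg,
    tension_low = lo, tension_high = hi
  )
}

#' Applied patch potential in cell-attached configuration
#'
#' In a cell-attached recording the potential across the patch is the resting
#' potential minus the pipette command potential.
#'
#' @param v_rest_mV Assumed resting potential (mV).
#' @param v_command_mV Pipette command potential (mV).
#'
#' @return Applied patch potential in mV.
#' @export
#' @examples
#' applied_potential(-70, 30) # -100 mV
applied_potential <- function(v_rest_mV, v_command_mV) {
  v_rest_mV - v_command_mV
}

#' Detect the activation-pressure threshold in a pressure-clamp recording
#'
#' Operationalizes the manual reading of pressure-ramp experiments: the
#' current noise is estimated on an initial baseline window, and the
#' activation threshold is the pressure at the first sample where the current
#' deviates from the baseline mean by more than `k_sigma` standard deviations
#' for at least `min_sustained_samples` consecutive samples. An optional
#' slope mode applies the same rule to the derivative of a low-passed copy of
#' the current, capturing a relevant change in trace slope rather than a
#' level change.
#'
#' @param rec Recording tibble with columns `time_s`, `pressure_mmhg`,
#'   `current_pa` (see [simulate_pressure_recording()] /
#'   [read_pressure_csv()]).
#' @param baseline_window_s Length of the initial baseline window in seconds
#'   (must precede any stimulation; default 0.5).
#' @param k_sigma Detection threshold in baseline standard deviations
#'   (default 5).
#' @param min_sustained_samples Number of consecutive supra-threshold samples
#'   required (default 25, i.e. 1 ms at 25 kHz).
#' @param mode `"level"` (default) or `"slope"`.
#'
#' @return One-row tibble with `detected` (logical), `threshold_mmHg` (`NA`
#'   when no activation is detected), `crossing_time_s`, `baseline_mean_pa`
#'   and `baseline_sd_pa`. No crossing is an explicit negative result, not an
#'   error.
#' @export
detect_activation_threshold <- function(rec,
                                        baseline_window_s = 0.5,
                                        k_sigma = 5,
                                        min_sustained_samples = 25,
                                        mode = c("level", "slope")) {
  mode <- match.arg(mode)
  if (k_sigma <= 0) stop("`k_sigma` must be > 0", call. = FALSE)
  req <- c("time_s", "pressure_mmhg", "current_pa")
  if (!all(req %in% names(rec))) {
    stop(
      "`rec` must have columns ",
      paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(diff(rec$time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  x <- rec$current_pa
  if (mode == "slope") {
    dt <- mean(diff(rec$time_s))
    lp <- gaussian_smooth(x, sigma = max(2, 2e-4 / dt)) # ~0.2 ms low-pass
    x <- c(diff(lp) / dt, 0)
  }
  in_baseline <- rec$time_s < rec$time_s[1] + baseline_window_s
  if (sum(in_baseline) < 2L) {
    stop("baseline window contains fewer than 2 samples", call. = FALSE)
  }
  mu <- mean(x[in_baseline])
  sigma <- pop_sd(x[in_baseline])
  dev <- abs(x - mu) > k_sigma * sigma
  no_hit <- tibble(
    detected = FALSE, threshold_mmHg = NA_real_,
    crossing_time_s = NA_real_, baseline_mean_pa = mu, baseline_sd_pa = sigma
  )
  if (!any(dev)) {
    return(no_hit)
  }
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_sustained_samples)
  if (!length(hit)) {
    return(no_hit)
  }
  first <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  tibble(
    detected = TRUE,
    threshold_mmHg = rec$pressure_mmhg[first],
    crossing_time_s = rec$time_s[first],
    baseline_mean_pa = mu, baseline_sd_pa = sigma
  )
}
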