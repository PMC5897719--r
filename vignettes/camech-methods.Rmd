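---
title: "Methods: calcium-event detection and membrane-tension estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-event detection and membrane-tension estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`camech` implements an end-to-end analysis of spontaneous calcium activity
in cultured neuronal networks, plus the membrane-tension biophysics used to
interpret pressure-clamp experiments on mechanosensitive channels. This
vignette documents the models, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not establish.

## The imaging pipeline

### Segmentation

Cells are located on the *temporal standard-deviation projection* of the
movie: for each pixel, the standard deviation of its intensity over all
frames. Any background that is static in time — however spatially
non-uniform — projects to the noise floor, while pixels whose fluorescence
fluctuates with calcium transients stand out. We use the population
convention (divide by the number of frames); the choice only rescales the
projection and does not affect anything downstream, but it is fixed and
documented for reproducibility.

Residual non-uniformity of the projection is estimated by *grayscale
morphological opening* (erosion, then dilation) with a Euclidean disk and
subtracted with clamping at zero. The opening removes bright features
smaller than the disk, so the disk radius (default 5 px) must stay below
the typical soma size — opening with a larger element would swallow the
cells into the "background". The structuring element is the set of integer
offsets with Euclidean norm at most the radius, and at image borders the
element is clipped to the image domain; with this convention the operator
remains anti-extensive, increasing and idempotent, which the test suite
checks against an independent brute-force implementation.

The cleaned projection is binarized with Otsu's threshold (parameter-free
and reproducible; an explicit `threshold` override exists), and foreground
pixels are grouped into 8-connected components. Components smaller than
`min_area_px` (default 5 px) are discarded and the survivors are relabelled
from 1 in raster-scan order of their first pixel, making label assignment
deterministic. A constant image yields an empty ROI set, not an error.
All coordinates in outputs are 0-based `(row, col)` pairs and frame indices
are 0-based, matching the conventions of the file formats we write.

### Baseline and ΔF/F₀

Per-ROI traces are the mean intensity over the ROI's pixels, frame by
frame. The baseline F₀ is a heavy linear-diffusion low-pass of the raw
trace. Because iterating the discrete heat equation to a cumulative
diffusion time *t* is equivalent to convolving with a Gaussian of
σ = √(2t), we implement the filter directly as a normalized Gaussian
convolution with σ = `window_s`/4 (in seconds; default window 30 s), so
that the ±2σ support of the kernel spans the stated window. Whether such a
baseline filter should be applied once or iterated is a genuine design
choice; the equal-diffusion-time construction makes the result independent
of how the diffusion is scheduled, which is why we chose it.

Boundaries are handled by half-sample symmetric reflection. Two exact
consequences are worth noting: a constant trace is reproduced exactly, and
the operator is doubly stochastic, so the trace mean is conserved. In the
interior (more than ~4σ from the ends) linear trends pass through the
filter unchanged, which keeps slow drifts in F₀ rather than in ΔF/F₀.
ΔF/F₀ is then `(F − F₀)/F₀`; a non-positive baseline anywhere is reported
as an error naming the offending ROI rather than producing silent `Inf`s.

### Perona–Malik de-noising

The normalized traces are de-noised with one-dimensional anisotropic
diffusion, `u ← u + step · ∇·(g(|∇u|) ∇u)` with conductance
`g(s) = 1/(1 + (s/κ)²)` and zero-flux (reflective) boundaries. Gradients
well below κ diffuse as under linear smoothing; gradients above κ are
preserved, so the sharp rise of a calcium transient survives while
frame-to-frame noise is flattened. The explicit scheme is stable and obeys
a discrete maximum principle for `step ≤ 0.5` (default 0.25), and the flux
form conserves the trace mean exactly; both guarantees are tested at
10⁻⁶ relative tolerance.

Parameters:

* `kappa` — defaults to `3 × mad(diff(dff))`, i.e. three times a robust
  estimate of the noise level of the trace *derivative*. The event
  detector thresholds the derivative, so tying κ to the derivative noise
  keeps the smoothing adaptive across noise levels. A noise-free trace has
  `mad(diff(dff)) = 0`; in that degenerate case the filter returns its
  input unchanged.
* `n_iter` — default 10. This is an operating-point choice: diffusion
  spreads the foot of a transient backward in time, and every iteration
  moves the first super-threshold derivative sample earlier. At 65 Hz,
  20 iterations displace detected onsets by roughly 5–6 frames relative to
  the true start of the rise, while 10 iterations suppress sub-κ noise
  with an onset bias of ~3 frames — inside the ±5-frame matching tolerance
  we use to validate the detector. Users smoothing slower or noisier data
  can raise `n_iter`; the onset bias scales with the effective smoothing
  width.

### Event detection

Events are detected on the smoothed trace with four conditions, applied to
the per-frame forward difference `d[t] = u[t+1] − u[t]` (per-frame
differences keep the published thresholds directly applicable):

1. **Onset** — `d` exceeds the onset threshold at *every* frame of a right
   interval of `onset_check_frames` after the candidate (strict reading;
   default 10 frames ≈ 150 ms at 65 Hz). The threshold is 10⁻³ per frame
   for asynchronous activity and 10⁻² for synchronous activity; the mode
   is an explicit user flag (default asynchronous) since the appropriate
   derivative scale is a property of the recording.
2. **Offset** — the first later time whose right-interval derivative is
   below −10⁻⁴ per frame throughout; this locates the decay.
3. **Amplitude** — the ΔF between the onset and the peak before the offset
   must exceed the noise threshold, defined as the population standard
   deviation of (raw − smoothed) over the whole trace. We measure the ΔF
   on the smoothed trace, consistent with the onset/offset being defined
   there.
4. **Width** — the gap between the last super-threshold derivative after
   the onset and the offset must stay below `max_rise_to_offset_frames`
   (default 300 frames). The natural-language statement of this rule is
   ambiguous about whether exceeding the width accepts or rejects; we
   implement reject-if-exceeded — a plateau that drifts for seconds
   between rise and decay is not a calcium transient — and the rule can be
   disabled by setting the width to `Inf`.

Accepted events are non-overlapping; the scan resumes after each offset.
The detector is deterministic, monotone in transient amplitude, and
threshold-monotone (switching asynchronous → synchronous can only remove
events); all three properties are exercised in the tests. Traces shorter
than the checking windows yield an empty train with a warning. The mean
firing rate is the event count divided by the trace duration, and the
raster is the long-format table of (ROI, onset time) pairs.

## Membrane-tension biophysics

For a membrane dome aspirated into a patch pipette, Laplace's law gives the
bilayer tension as τ = γ + rP/2, with r the pipette tip radius, P the
suction magnitude, and γ the membrane–glass adhesion energy. The unit chain
is `τ[mN/m] = γ[mN/m] + (r[m]·P[Pa]/2)·10³`; pressures are stored as
positive suction magnitudes in mmHg (1 mmHg = 133.322 Pa) and converted
internally. `tension_range()` evaluates the estimate at the extreme
adhesion energies considered plausible for the preparation — 1.6 mN·m⁻¹
for a neuronal membrane and 3.7 mN·m⁻¹ for a homogeneous phospholipid
bilayer — bracketing the truth.

Reported tensions use a two-stage rule: round to two decimals, then
truncate toward zero at one decimal. This is the reporting convention that
reproduces, at both pressure levels, the published one-decimal values that
the estimator is validated against (13.699 → 13.7 but 8.366 → 8.3); pure
one-decimal truncation or rounding each fail at one of the two levels. Raw
values are always available (`report = FALSE`, the default).

The *activation-pressure threshold* of a mechanosensitive current during a
suction ramp is determined in published work by visual inspection of where
the first evoked current appears. `detect_activation_threshold()`
operationalizes this: current noise is estimated on an initial baseline
window (default 0.5 s, which must precede stimulation), and the threshold
is the pressure at the first sample where |current − baseline mean|
exceeds `k_sigma` (default 5) baseline standard deviations for at least
`min_sustained_samples` consecutive samples (default 25, i.e. 1 ms at the
nominal 25 kHz). The sustained-run requirement makes isolated noise spikes
powerless: a false trigger requires 25 consecutive 5σ excursions. The
"relevant change in trace slope" variant is available as `mode = "slope"`
(the same rule applied to the derivative of a low-passed current). Absence
of a crossing is an explicit negative result (`detected = FALSE`), not an
error, and the detector is invariant to constant current offsets and
non-decreasing in `k_sigma`.

The cell-attached applied potential is `V_rest − V_command`; with a
−70 mV resting assumption and a +30 mV command this gives −100 mV.

## Statistics

`mann_whitney_two_sided()` wraps the standard rank-sum machinery with an
explicit policy: exact enumeration of the null distribution when
`n_a·n_b ≤ 400` and the pooled sample is tie-free, otherwise the normal
approximation with midrank tie correction and continuity correction. The
exact path is validated against brute-force permutation enumeration over
all `C(n_a+n_b, n_a)` labelings for samples up to size 8. Summaries are
mean ± s.e.m. with the (n−1) standard deviation and `sem = 0` for a single
observation. Pearson colocalization is the plain correlation over
(optionally masked) pixel pairs and refuses degenerate inputs (fewer than
3 pixels, or zero variance in a channel) rather than returning `NaN`.
Viability and synapse-ratio helpers compute per-field percentages and
VGAT:VGLUT1 ratios and summarize across fields.

## The synthetic-data generator

`simulate_movie()` renders somata as 2-D Gaussian profiles
(σ = `cell_radius_px`/2, so the nominal radius is the 2σ disk) on a static
field. A pixel's intensity is

```
baseline_level · (1 + G(x) · (resting_contrast + ΔF/F₀(t)))
  + background_gradient · (row + col) + noise
```

so at a soma center the fluorescence tracks `baseline·(1 + ΔF/F₀)`. Event
times are Poisson with rate `event_rate_hz`; each event adds a transient
kernel with a linear rise over `rise_frames` and an exponential decay with
`decay_tau_s` — a shape chosen because it exercises all four detector
conditions (sustained positive derivative, amplitude, negative-derivative
offset, bounded rise-to-offset gap), not because indicator kinetics were
measured. Noise is additive i.i.d. Gaussian (EMCCD data at high gain are
near-Gaussian; Poisson shot noise is omitted for test determinism), the
background plane is static in time so the standard-deviation projection is
background-free by construction, and all intensities are clipped at zero.
Simulations are bit-reproducible given the seed.

Defaults are calibration-free choices meant to be *realistic for a mature
cortical culture imaged at 65 Hz*, not measurements: 0.1 Hz spontaneous
event rate, transient amplitude 0.5 ΔF/F₀ with 1 s decay and a 10-frame
rise, baseline 100 a.u. with noise sd 1 a.u. With these settings the
per-trace ΔF/F₀ noise is of order 4×10⁻³ — the transient amplitude sits
roughly two orders of magnitude above the detector's noise threshold,
which is the regime the detector's published thresholds presuppose. Cell
centers are placed with a minimum separation of 4 cell radii by default so
that ROI-count recovery is exact and segmentation failures cannot be
confounded with overlap.

What passing the round-trip tests shows: the segmentation recovers
well-separated active cells exactly, and the detector recovers Poisson
event trains at high SNR with ≥0.9 recall and precision under ±5-frame
onset matching. What it does not show: performance under bleaching, motion,
neuropil contamination, overlapping somata, dye saturation, or amplitudes
near the noise threshold — none of which the generator emulates.
Published group-level quantities from laboratory recordings (firing-rate
bar heights, activation-threshold means, colocalization coefficients,
viability percentages, synapse ratios) depend on undeposited raw data and
are therefore covered only by these synthetic surrogates and by the
analytic reproductions above.

`simulate_pressure_recording()` produces a linear ramp from zero with a
clean current step at the programmed threshold plus Gaussian noise;
`simulate_coloc_pair()` draws pixel pairs from a bivariate normal with the
target correlation (exact affine dependence at |ρ| = 1).

## Problem sizes and tolerances

The validation suite runs at deliberately chosen sizes: one 10-cell,
600 s, 65 Hz movie (64×64 px) for the detector round trip; 200 random
≤12×12 images for the exact opening oracle; 50 random tie-free sample
pairs (sizes ≤ 8) for the exact Mann–Whitney oracle; 10⁴-pixel image pairs
at ρ ∈ {0, 0.5, 0.86} with a 0.05 recovery band (the 1/√n sampling scale);
and 20 simulated ramps at 50:1 SNR with a ±2 mmHg recovery band. Filter
guarantees are asserted at 10⁻⁶ relative (mean conservation, max
principle), exactness for constants, and 1% for interior linear ramps.

## Known limitations

* The segmentation assumes temporally static background; slow focus drift
  or bleaching would leak into the standard-deviation projection (bleaching
  of the *trace* is absorbed by the 30 s baseline, but spatial bleaching
  gradients are not modelled).
* Overlapping or touching somata are not demixed; they merge into one ROI.
* The event detector reports onset/offset times, not spike times; no
  deconvolution is attempted.
* Sub-conductance structure of mechanosensitive currents (partial vs full
  openings) is outside scope; only the first activation threshold is
  detected.
* The Laplace-law estimate inherits the uncertainty of the nominal pipette
  radius and treats the adhesion energy as a known bracket.
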