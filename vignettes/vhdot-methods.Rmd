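---
title: "Methods: forward modelling, reconstruction, and benchmarking of very high-density DOT arrays"
author: "vhdot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward modelling, reconstruction, and benchmarking of very high-density DOT arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diffuse optical tomography (DOT) reconstructs changes in cerebral
haemoglobin concentration from near-infrared light measurements made
between source and detector fibres on the scalp. Image quality is governed
by measurement density: packing optodes more tightly yields more
overlapping, multi-distance channels and therefore better-conditioned
inverse problems. `vhdot` implements the computational chain needed to
design and evaluate such arrays — in particular to compare a
very-high-density (VHD) checkerboard lattice at 9.75 mm pitch against the
conventional high-density (HD) 13 mm pitch — and to analyse the channel
data those arrays produce, from raw intensities through haemoglobin images,
task maps, and spatiotemporal decoding.

Everything runs on synthetic data with known ground truth; no external
recordings are needed. The geometry is deliberately planar: the curved,
multi-panel caps used on real heads are flattened to one rectangular
lattice over a slab, because the analytic forward model below requires a
planar boundary and the density question is a property of the lattice
pitch, not of the cap curvature. The consequences of that choice are
discussed at the end.

# Forward model

## Photon diffusion in a semi-infinite slab

The phantom ([`slab_phantom()`]) is a rectangular slab with the boundary at
z = 0 and depth increasing into the tissue, split into a superficial
(scalp/skull) layer — 10 mm by default — and "brain" below. Baseline
optical properties are typical adult-head values at the two laser lines:

| wavelength | mu_a (mm^-1) | mu_s' (mm^-1) |
|-----------:|-------------:|--------------:|
| 685 nm     | 0.019        | 1.31          |
| 830 nm     | 0.021        | 1.07          |

For continuous-wave light the fluence from a point source obeys the
diffusion equation; for a homogeneous semi-infinite medium the Green's
function is the familiar image-source construction with an extrapolated
boundary:

* diffusion coefficient `D = 1/(3 (mu_a + mu_s'))`,
* effective attenuation `mu_eff = sqrt(mu_a / D)`,
* effective isotropic source one transport mean free path deep,
  `z0 = 1/mu_s'`,
* extrapolated boundary offset `z_b = 2 D (1 + R_eff)/(1 - R_eff)` with
  `R_eff = 0.493` (air–tissue refractive mismatch),
* `G(r) = [exp(-mu_eff r1)/r1 - exp(-mu_eff r2)/r2] / (4 pi D)`, where
  `r1` is the distance to the real source and `r2` to its negative image
  mirrored about `z = -z_b`.

## The sensitivity (Jacobian) matrix

The Rytov linearization relates a small absorption change `x` (mm^-1, per
voxel) to the change in each channel's log-ratio measurement, `y = A x`.
[`slab_sensitivity()`] builds `A` by the adjoint product

```
A[m, v] = G(source_m, voxel_v) * G(voxel_v, detector_m) * h_v / G(source_m, detector_m)
```

with `h_v` the voxel volume. Numerical guards: source–voxel distances are
clamped at half a voxel spacing (the Green's function has a 1/r
singularity), and the rare negative products left by the image-source
subtraction are clamped to zero, so `A` is nonnegative and every channel
row is active. A brute-force per-entry oracle in the test suite checks the
vectorized assembly to 1e-10 relative.

For large phantoms the Jacobian is never materialized at once:
`blocked_slab_system()` precomputes the per-optode fluence matrix
(optodes x voxels) and produces Jacobian columns on demand, so the
96,000-voxel benchmark below runs comfortably in a few hundred MB.

## Measurement noise

Channel noise ([`noise_model()`]) is zero-mean Gaussian, independent across
channels and frames, with a standard deviation that grows exponentially
with source–detector separation, mirroring the log-linear light fall-off:
`sigma(d) = sigma_ref * exp((d - d_ref)/tau)`, defaults
`sigma_ref = 0.0075` (log-ratio units) at `d_ref = 10` mm with
`tau = 15` mm. The exponential form and its parameters are this package's
declared stand-in for empirically tabulated channel noise; all three
numbers are user-configurable. Cross-channel covariance is zero by
construction, and the simulator's output is verified against `sigma(d)` to
5% at 10,000 frames.

# Image reconstruction

## Tikhonov with spatially-variant regularization

The inverse operator ([`inverse_operator()`]) follows the high-density DOT
convention. With `c_v = diag(A'A)_v` the per-voxel sensitivity energy:

```
L_v  = sqrt(c_v + lambda2 * max_v(c_v))      # spatially-variant scale
A~   = A diag(1/L)                           # column-normalized Jacobian
x    = diag(1/L) A~' (A~ A~' + lambda1 * s * I)^-1 y
```

where `s` is by default the largest eigenvalue of `A~A~'`. Defaults are
`lambda1 = 0.01` and `lambda2 = 0.1`.

Two observations matter for interpretation:

* `lambda2` interpolates between **full column normalization**
  (`lambda2 = 0`: every voxel's column has unit norm, the most aggressive
  depth compensation, which over-boosts poorly sensed deep voxels under
  noise) and the **pure-Tikhonov limit** (`lambda2 -> Inf`: `L` constant,
  no depth compensation, maximal surface bias). The default 0.1 sits
  between the two, and the test suite verifies that it localizes a deep
  target strictly deeper than the pure-Tikhonov limit.
* how `lambda1` is scaled is a genuinely open convention; the package
  defaults to scaling by the largest eigenvalue of `A~A~'` (so `lambda1`
  is a fraction of the operator's largest singular value squared) and also
  offers `smax_scale = "diag"` (largest diagonal entry) and `"none"`
  (unscaled). This is the single most consequential reconstruction choice:
  the eigenvalue scaling gives the strongest smoothing at fixed `lambda1`,
  and absolute point-spread-function widths shift by 1–2 mm across the
  three conventions (the relative VHD-vs-HD ordering does not).

The operator is factored once (Cholesky of the regularized Gram matrix);
each reconstruction is a triangular solve plus a back-projection, and a
brute-force dense evaluation of the closed form is the oracle in the test
suite (1e-8 relative on toy systems).

## Spectroscopy

Per voxel, the two-wavelength absorption pair is converted to oxy- and
deoxy-haemoglobin by inverting the 2x2 extinction matrix, `dC = E^-1 x`;
total haemoglobin is their sum. `E` is packaged from the standard compiled
haemoglobin molar extinction spectra at 685/830 nm, converted to
natural-log base (mm^-1 M^-1) because the measurements are natural-log
ratios; any 2x2 matrix can be substituted. The forward-then-inverse round
trip is exact to machine precision, and the noiseless end-to-end chain
(simulate, reconstruct, spectroscopy) recovers a planted
dHbR/dHbO = -0.3 amplitude ratio within 15%.

# PSF image-quality benchmarking

[`psf_study()`] reconstructs single-voxel perturbations seeded across the
slab and scores each point-spread function with four metrics
([`psf_fwhm()`], [`psf_localization_error()`],
[`psf_effective_resolution()`], [`psf_snr()`]):

* **FWHM** — default "equiv-sphere" mode: the diameter `(6V/pi)^(1/3)` of
  the sphere whose volume V equals that of the region at or above 50% of
  the PSF maximum. PSFs are anisotropic, so a volumetric equivalent is more
  stable than any single profile width; a "max-extent" mode (largest
  centre-to-centre distance plus one voxel) is provided because either
  convention is defensible.
* **Localization error** — distance from the true perturbation to the
  intensity-weighted centroid of the >= 50% region (full-volume centroids
  are dominated by reconstruction ripple, hence the restriction).
* **Effective resolution** — diameter of the sphere centred on the true
  position needed to cover the >= 50% region; each voxel's covering radius
  includes its half-diagonal, so a delta reconstructed exactly in place
  scores one voxel diagonal rather than zero. This is always at least the
  localization error.
* **SNR** — mean PSF value over the >= 50% region divided by the mean
  per-voxel standard deviation of noise-only reconstructions over the same
  region. PSFs themselves are reconstructed noiselessly; the noise enters
  through a separate stack of 50 pure-noise reconstructions (shared across
  seeds — the noise statistics do not depend on the seed), with
  Monte-Carlo wobble of a few percent at that stack size.

The density benchmark runs both pitches over a 160 x 160 x 30 mm slab at
2 mm voxels (96,000 voxels; roughly 2,800 channels at 9.75 mm pitch and
1,100 at 13 mm under the 40 mm separation cutoff), seeds on a 16 mm
lateral lattice 30 mm in from the edges, every 2 mm slice in the 5–25 mm
analysis band, perturbation amplitude 0.01 mm^-1. Metrics are summarized
as per-depth-bin medians ([`depth_profile()`], 5 mm bins). These problem
sizes keep the full two-pitch comparison to a few minutes on one core.

**What the comparison shows — and a known limitation.** On this benchmark
the denser lattice is uniformly better in localization error, effective
resolution, and SNR, and better in FWHM over the shallow and middle depth
bins. The FWHM contrast between the pitches is however much weaker than
reported for curved multi-panel caps on head models: on a gapless planar
lattice the regularized PSF width at depth is dominated by the
regularization kernel, which depends only weakly on pitch, whereas real
multi-panel caps have inter-panel coverage gaps and curvature that
penalize the sparser array much more. The flattened-slab design choice
buys an analytic, dependency-free forward model at the cost of
understating the sparse array's FWHM penalty; the deepest bin can even
reverse by a fraction of a millimetre. Treat the FWHM arm of the planar
benchmark as conservative.

# Measurement preprocessing

The standard chain ([`preprocess_run()`]) is:

1. **Log-mean ratios** ([`logmean_ratio()`]): `y = -ln(Phi / mean_t Phi)`
   with the temporal mean taken as the *geometric* mean, so every output
   channel has exactly zero log-mean (for fluctuations of a few percent
   the geometric and arithmetic means agree to second order).
2. **Noisy-channel rejection** ([`reject_noisy_channels()`]): a channel is
   dropped when its temporal standard deviation exceeds 7.5% (0.075 in
   natural-log units, the standard reading of the percent threshold);
   subjects fall below quality when run retention drops under 80%. The
   threshold is applied to raw log-ratios before filtering (the ordering
   is configurable, as the convention varies).
3. **Detrend and band-pass** ([`temporal_filter()`]): linear detrend, then
   zero-phase 3rd-order Butterworth high-pass at 0.02 Hz and low-pass at
   1 Hz. The zero-phase filter is implemented in the package
   (odd-reflection edge padding plus steady-state initial conditions,
   direct-form-II transposed, vectorized over channels) because a naive
   forward–backward pass with zero initial state leaves edge transients of
   the order of the signal itself for near-DC content.
4. **Superficial signal regression** ([`superficial_signal_regression()`]):
   the mean of the first-nearest-neighbour channels — scalp-dominated at
   ~ one pitch separation — is the global superficial regressor; each
   channel's least-squares slope on the *centred* regressor is subtracted,
   which leaves every output channel exactly uncorrelated with the
   regressor and exactly annihilates any channel proportional to it.
5. **Final low-pass and downsampling** ([`final_filter_downsample()`]):
   zero-phase 0.2 Hz low-pass, then interpolation onto a uniform 1 Hz time
   base starting at the first input frame (after a 0.2 Hz anti-alias
   filter the interpolation error is negligible, and this keeps the output
   grid exact: a 600 s run yields exactly 600 frames).

Re-running the chain on already-processed data changes mid-passband
content by 1–2% RMS; the residual is re-estimated superficial-regression
slopes (finite-window estimation error), not filter distortion. Content
near the band edges is attenuated again on every pass — that is filter
physics, and the reason the package's property test constrains its probe
signals to the middle of the passband.

Run-level quality metrics: [`pulse_snr()`] scores the cardiac band
(0.5–2 Hz) against the bandwidth-scaled median periodogram level of the
flanking bands (0.25–0.5 and 2–3 Hz, a configurable choice), in dB;
[`light_falloff()`] summarizes mean intensity versus separation with a
log-linear slope and the dynamic range.

# Task mapping

[`build_design_matrix()`] convolves per-condition boxcars with the
haemodynamic response function and adds constant and linear-drift columns.
The default HRF ([`canonical_hrf()`]) is a double-gamma parameterized by
its peak times — positive lobe at 6 s, undershoot at 16 s, undershoot
ratio 1/6, unit peak — and is an argument everywhere, so an empirically
tabulated response can be substituted. [`fit_glm()`] is per-voxel ordinary
least squares with standard errors from the residual variance and
`(X'X)^-1`, with a 1e-12 floor so noiseless synthetic fits do not divide
by zero downstream. Group maps combine subjects as fixed effects,
`t = sum(beta) / sqrt(sum(se^2))` by default with an
inverse-variance-weighted alternative (the two agree when subjects share
standard errors). [`dice_overlap()`] binarizes each map at a fraction of
its own maximum (0.25 or 0.5 conventionally) and [`roi_block_average()`]
extracts block-locked chromophore traces from a t-map-defined region,
reporting across-block standard errors.

# Template-matching decoding

Blocks are interleaved odd/train, even/test
([`split_blocks_interleaved()`]); each block window drops the first 4 s
(onset transient) and keeps 16 s ([`extract_block_window()`]); training
blocks average into one voxel x time template per task. A trial is scored
against each template by the spatial Pearson correlation at each time
point ([`classify_trial()`]); how those per-time-point correlations are
aggregated is ambiguous in practice, so the package offers mean over time
(default), max over time, and flattened spatiotemporal correlation. Ties
break by template order and are flagged, which keeps decoding
deterministic. Longer lateralized protocols are truncated to their first 6
blocks and 30 s for protocol parity. Movie-style decoding
([`decode_movie()`]) segments two viewings of the same run into
2/4/8/15/30 clips (nominal durations 300/150/75/40/20 s for a 10-minute
run), excludes the first 6 s of each segment, uses first-viewing segments
as templates for the time-aligned second-viewing segments, and reports a
confusion matrix with chance 1/n.

# Naturalistic feature regressors

Luminance is the per-frame grayscale mean (standard luma weights
0.299/0.587/0.114). The auditory envelope passes the waveform through 25
log-spaced bands from 100 Hz to 8 kHz — implemented as FFT-domain analytic
band signals, which remain numerically stable for narrow low-frequency
bands where high-order recursive band-passes are not — and averages the
per-band log power. Rated binary features combine by majority vote with
tied bins flagged for re-evaluation. Every raw trace is HRF-convolved
(with steady-state edge handling so constants do not produce onset ramps)
and band-passed to 0.02–0.2 Hz to match the reconstructed data
([`regressor_pipeline()`]), then correlated voxelwise
([`feature_correlation_map()`]). Run repeatability is the per-voxel
Pearson correlation between viewings, combined across subjects on
Fisher-z values.

# The synthetic session generator

[`make_session()`] composes the whole forward chain into complete
two-wavelength sessions with known ground truth:

* geometry: one 6 x 6 checkerboard pad at 9.75 mm pitch centred over a
  72 x 72 x 30 mm slab at 3 mm voxels (configurable);
* activation: spherical ROIs confined to the brain layer, driven by the
  HRF-convolved block design, with the canonical amplitude pattern
  dHbO = +1 uM, dHbR = -0.3 uM; absorption via the extinction matrix;
* superficial signal: a band-limited (0.08–0.12 Hz) random walk shared
  across channels, coupled with a weight decaying exponentially with
  separation (20 mm scale) so it loads most on nn1 channels — exactly the
  structure superficial signal regression targets; SD 0.01 at nn1;
* cardiac component: a shared sinusoid near 1 Hz with the same
  distance-decaying coupling, amplitude 0.03 at nn1 (a ~3% intensity
  modulation), chosen so the band-limited pulse SNR on short channels
  falls in the 10–30 dB range characteristic of well-coupled in-vivo
  recordings;
* channel noise from the packaged `sigma(d)` model; frame rate 7.8 Hz;
* a raw-intensity view `Phi = Phi0 * 10^(-d/5mm) * exp(-y)`, one decade of
  light per 5 mm of separation, giving the familiar log-linear fall-off
  and a 10^5–10^6 dynamic range across the channel set.

Sessions are deterministic functions of (spec, seed).
[`make_movie_session()`] generates run pairs sharing a stimulus-driven
spatiotemporal component built from ground-truth feature traces (a smooth
luminance-like trace and a binary speech-like trace), scaled so the
channel-level SNR at the most strongly driven wavelength matches the
request, plus independent noise per run.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: head curvature and multi-panel coverage
gaps, heterogeneous five-layer anatomy, optode-scalp coupling variation,
motion artifacts, correlated (systemic) physiological noise across
channels beyond the single superficial component, and any nonlinearity of
the Rytov approximation for large absorption changes. Results here
validate the computational chain, not the hardware.

# Numerical choices

* Source–voxel distance clamp: half a voxel spacing; negative adjoint
  products clamped to zero.
* Largest eigenvalue: exact (`eigen`) up to 512 channels, deterministic
  power iteration (tolerance 1e-10) beyond.
* Gram matrix and back-projection assembled in voxel blocks (default
  8,192 columns) so peak memory stays at a few channel x block matrices.
* Zero-phase filtering: 3rd-order Butterworth coefficients from
  `signal::butter`, applied with the package's own
  padding-plus-initial-conditions forward–backward pass.
* GLM standard-error floor 1e-12; decoding ties broken by template order
  and flagged; degenerate (zero-variance) time points skipped in scoring;
  zero-variance voxels get correlation 0 with an `undefined` flag.
* All stochastic stages take explicit integer seeds and restore the
  caller's RNG state.

# Known limitations

The planar slab understates the sparse array's FWHM penalty (discussed
above); the analytic homogeneous forward model cannot represent
layer-specific partial pathlengths; the noise model is white in time and
diagonal across channels; grid alignment by Dice search is over a
user-supplied candidate list rather than a gradient scheme; and the
SNIRF-schema container is serialized as JSON rather than HDF5, preserving
the group/dataset layout but not binary compatibility with HDF5 readers.
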