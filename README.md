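# vhdot

Simulation and analysis pipeline for very high-density diffuse optical
tomography (VHD-DOT).

Functional near-infrared imaging reconstructs changes in cerebral oxy- and
deoxy-haemoglobin from light measurements between source and detector
fibres on the scalp. Image quality is set by measurement density: a
checkerboard lattice at 9.75 mm pitch (VHD) yields roughly four times the
channel count of the conventional 13 mm high-density (HD) lattice and
correspondingly sharper, better-localized images. `vhdot` is for
researchers designing such arrays and analysing the data they produce: it
implements the forward light model, the regularized image reconstruction,
the point-spread-function (PSF) benchmarking used to compare array
designs, the full measurement preprocessing chain, GLM task mapping, and
spatiotemporal template-matching decoding — all exercised end to end on a
synthetic session generator with known ground truth, so nothing requires
external recordings.

## The model

**Forward.** For continuous-wave DOT the Rytov linearization relates a
voxelwise absorption change `x` (mm⁻¹) to channel log-ratio changes:

    y = A x + n

`A` is the sensitivity (Jacobian) matrix, built analytically for a
semi-infinite slab from photon-diffusion Green's functions with an
extrapolated boundary:
`A[m,v] = G(s_m, r_v) G(r_v, d_m) h_v / G(s_m, d_m)`. The noise `n` is
independent Gaussian per channel with standard deviation growing
exponentially with source–detector separation,
`σ(d) = σ_ref exp((d − d_ref)/τ)`.

**Inverse.** Tikhonov regularization with a spatially-variant term that
counteracts the surface bias of depth-dependent sensitivity:

    L_v = sqrt( diag(AᵀA)_v + λ₂ · max diag(AᵀA) )
    Ã   = A diag(1/L)
    x̂   = diag(1/L) Ãᵀ (ÃÃᵀ + λ₁ s_max I)⁻¹ y

with `λ₁ = 0.01`, `λ₂ = 0.1`, and `s_max` the largest eigenvalue of
`ÃÃᵀ`.

**Spectroscopy.** Per voxel, two-wavelength absorption maps to haemoglobin
via the extinction matrix: `ΔC = E⁻¹ x`, `ΔHbT = ΔHbO + ΔHbR`.

**Image quality.** Single-voxel perturbations are reconstructed across the
slab and scored by FWHM (equivalent-sphere diameter of the half-maximum
region), localization error (centroid offset), effective resolution
(covering-sphere diameter about the true position), and SNR (half-maximum
region signal over noise-only reconstruction spread), each summarized as
median versus depth over 5–25 mm.

## Worked example

Generate a synthetic auditory-task session (6 × 15 s blocks, two
wavelengths, distance-dependent noise, scalp signal, ~1 Hz cardiac
component), check data quality, reconstruct haemoglobin images, and map
the response:

```r
library(vhdot)

ses <- make_session(session_spec(), seed = 7)
ses
#> <dot_session> 448 channels x 1521 frames @ 7.8 Hz, 1 ROI(s), seed 7

reject_noisy_channels(logmean_ratio(ses$raw[["830"]]))
#> <channel_mask> 224/224 channels kept (retention 100.0%)
median(pulse_snr(ses$y[["830"]])[ses$y[["830"]]$channels$nn_class == 1])
#> 15.1   # dB: the planted cardiac component is clearly visible

ops <- lapply(ses$A, inverse_operator)
xs <- lapply(c("685", "830"), function(w) {
  y <- final_filter_downsample(
    superficial_signal_regression(temporal_filter(ses$y[[w]])))
  reconstruct(ops[[w]], y)
})
hb <- spectroscopy(xs[[1]], xs[[2]])
hb$HbO
#> <voxel_image> 5760 voxels x 195 frames [dHbO], range [-7.42e-06, 5.14e-06]

X <- build_design_matrix(ses$design, seq_len(ncol(hb$HbO$values)) - 1)
fit <- fit_glm(hb$HbO, X)
voxel_centers(ses$phantom)[which.max(fit$beta[, "auditory"]), ]
#>  x    y    z
#> 40.5 31.5  7.5   # mm; planted ROI centre was (36, 36, 14)
```

The peak HbO beta lands ~8 mm from the planted activation centre — inside
the array's effective resolution at that depth — and the HbR/HbO beta
ratio at the peak is −0.32 against the planted −0.3.

Compare array designs:

```r
vhd <- psf_study(9.75)   # 160 x 160 x 30 mm slab, 2 mm voxels
hd  <- psf_study(13)
depth_profile(list(vhd = vhd, hd = hd))
```

Six-way decoding of noiseless localizer sessions reaches 100% accuracy
against 16.7% chance (see `decode_localizer_session()`), and movie-style
segment decoding degrades from 2-way toward 30-way exactly as the
template-matching model predicts (`decode_movie()`).

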