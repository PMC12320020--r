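# Naturalistic stimulus feature regressors (luminance, auditory envelope,
# rated binary features), the regressor processing pipeline, voxelwise
# feature-correlation maps, and run-repeatability maps.

#' Frame-wise luminance trace
#'
#' Mean grayscale intensity of each video frame (standard luma weights
#' 0.299 R + 0.587 G + 0.114 B for colour frames), resampled to the target
#' rate by averaging frames within each output bin.
#'
#' @param frames list of frames: each either a matrix (grayscale) or an
#'   h x w x 3 array (RGB).
#' @param fps frame rate of the input frames, Hz.
#' @param fs_out output rate (default 1 Hz).
#' @return object of class `feature_regressor`: list with `name`, `values`,
#'   `fs`, `processed` flag.
#' @export
luminance_trace <- function(frames, fps, fs_out = 1) {
  if (length(frames) == 0) stop("no frames")
  lum <- vapply(frames, function(f) {
    if (length(dim(f)) == 3)
      mean(0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3])
    else mean(f)
  }, numeric(1))
  feature_regressor("luminance", bin_to_rate(lum, fps, fs_out), fs_out)
}

feature_regressor <- function(name, values, fs, processed = FALSE) {
  structure(list(name = name, values = as.numeric(values), fs = fs,
                 processed = processed),
            class = "feature_regressor")
}

#' @export
print.feature_regressor <- function(x, ...) {
  cat(sprintf("<feature_regressor> %s: %d samples @ %g Hz%s\n",
              x$name, length(x$values), x$fs,
              if (x$processed) " (HRF-convolved, band-passed)" else " (raw)"))
  invisible(x)
}

# average consecutive samples into bins of the output rate
bin_to_rate <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  per <- fs_in / fs_out
  n_out <- floor(length(x) / per)
  vapply(seq_len(n_out), function(k) {
    i0 <- floor((k - 1) * per) + 1
    i1 <- floor(k * per)
    mean(x[i0:i1])
  }, numeric(1))
}

# band-limited analytic signal via FFT masking: keep positive frequencies in
# [lo, hi) doubled, zero elsewhere; |result| is the band envelope. Spectral
# masking keeps narrow low-frequency bands numerically stable where high-order
# recursive band-passes are not.
band_envelope <- function(X, freqs, lo, hi, n) {
  mask <- complex(length(X))
  sel <- freqs >= lo & freqs < hi
  mask[sel] <- 2 * X[sel]
  Mod(stats::fft(mask, inverse = TRUE) / n)
}

#' Auditory log-power envelope
#'
#' Passes the waveform through a bank of `n_bands` log-spaced band-pass
#' filters (implemented as FFT-domain analytic band signals), extracts each
#' band's envelope, converts to logarithmic power, averages across bands, and
#' bins the result to the output rate.
#'
#' @param waveform numeric audio samples.
#' @param fs_audio audio sample rate, Hz; must exceed twice the top band
#'   edge.
#' @param n_bands number of filterbank bands (default 25).
#' @param flim frequency range of the bank, Hz (default 100-8000).
#' @param fs_out output rate (default 1 Hz).
#' @param floor_db silence floor for the log power, dB relative to full
#'   scale.
#' @return a `feature_regressor` (raw); silent input yields a constant
#'   floor-clamped trace with attribute `silent = TRUE`.
#' @export
audio_envelope <- function(waveform, fs_audio, n_bands = 25,
                           flim = c(100, 8000), fs_out = 1,
                           floor_db = -120) {
  if (fs_audio <= 2 * flim[2])
    stop("sample rate must exceed twice the top band edge")
  edges <- exp(seq(log(flim[1]), log(flim[2]), length.out = n_bands + 1))
  silent <- all(waveform == 0)
  n <- length(waveform)
  logpow <- matrix(floor_db, n_bands, n)
  if (!silent) {
    X <- stats::fft(waveform)
    freqs <- (seq_len(n) - 1) * fs_audio / n
    for (b in seq_len(n_bands)) {
      env2 <- band_envelope(X, freqs, edges[b], edges[b + 1], n)^2
      logpow[b, ] <- pmax(10 * log10(env2 + 10^(floor_db / 10)), floor_db)
    }
  }
  trace <- colMeans(logpow)
  reg <- feature_regressor("audio_envelope",
                           bin_to_rate(trace, fs_audio, fs_out), fs_out)
  attr(reg, "silent") <- silent
  reg
}

#' Consensus of binary feature ratings
#'
#' Majority vote across raters per 1-second bin; tied bins are listed for
#' re-evaluation and resolved by the configured rule.
#'
#' @param ratings raters x bins matrix of 0/1 ratings.
#' @param tie_rule "present" (ties count as 1), "absent" (0), the default
#'   being "absent".
#' @return a `feature_regressor` (raw, 1 Hz) with attribute `reevaluate`
#'   (bin indices where raters tied).
#' @export
binary_feature_consensus <- function(ratings, tie_rule = c("absent", "present")) {
  tie_rule <- match.arg(tie_rule)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 1) stop("at least one rater is required")
  if (!all(ratings %in% c(0, 1))) stop("ratings must be binary")
  votes <- colMeans(ratings)
  ties <- which(votes == 0.5)
  cons <- as.numeric(votes > 0.5)
  if (tie_rule == "present") cons[ties] <- 1
  reg <- feature_regressor("binary_feature", cons, fs = 1)
  attr(reg, "reevaluate") <- ties
  reg
}

#' Process a raw feature trace into a GLM-ready regressor
#'
#' Convolves the raw trace with the HRF, band-pass filters it (zero-phase
#' Butterworth) to match the reconstructed-data passband, and removes the
#' mean.
#'
#' @param reg a `feature_regressor` (raw) or numeric vector at `fs`.
#' @param hrf function(t); default [canonical_hrf()].
#' @param band band-pass edges in Hz (default 0.02-0.2).
#' @param fs sample rate when `reg` is a bare vector (default 1 Hz).
#' @param hrf_span_s HRF kernel length, s.
#' @return a processed `feature_regressor` (zero mean).
#' @export
regressor_pipeline <- function(reg, hrf = canonical_hrf, band = c(0.02, 0.2),
                               fs = 1, hrf_span_s = 32) {
  if (inherits(reg, "feature_regressor")) {
    x <- reg$values; fs <- reg$fs; nm <- reg$name
  } else { x <- as.numeric(reg); nm <- "feature" }
  kern <- hrf(seq(0, hrf_span_s, by = 1 / fs))
  if (length(x) < length(kern)) stop("trace shorter than the HRF kernel")
  # steady-state edge handling: extend the first value backwards so a
  # constant trace convolves to a constant (no onset ramp artifact)
  K <- length(kern)
  xp <- c(rep(x[1], K), x)
  conv <- stats::convolve(xp, rev(kern), type = "open")[K + seq_along(x)] / fs
  v <- matrix(conv, 1)
  v <- butter_filtfilt(v, fs, band[1], "high")
  v <- butter_filtfilt(v, fs, band[2], "low")
  out <- as.vector(v) - mean(v)
  feature_regressor(nm, out, fs, processed = TRUE)
}

#' Voxelwise feature-correlation map
#'
#' Pearson correlation between a (processed) feature regressor and every
#' voxel's time series. Zero-variance voxels get r = 0 and are flagged.
#'
#' @param reg a `feature_regressor` or numeric vector.
#' @param series voxels x frames matrix or `voxel_image` at the regressor's
#'   rate.
#' @return numeric vector of correlations in [-1, 1]; attribute `undefined`
#'   holds indices of zero-variance voxels.
#' @export
feature_correlation_map <- function(reg, series) {
  x <- if (inherits(reg, "feature_regressor")) reg$values else as.numeric(reg)
  m <- if (inherits(series, "voxel_image")) series$values else as.matrix(series)
  if (length(x) != ncol(m)) stop("regressor and series lengths differ")
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  mc <- m - rowMeans(m)
  sv <- sqrt(rowSums(mc^2))
  r <- unname(as.vector(mc %*% xc) / (sv * sx))
  r <- pmin(pmax(r, -1), 1)
  und <- unname(which(sv == 0))
  r[und] <- 0
  attr(r, "undefined") <- und
  r
}

#' Fisher z-transform and inverse
#'
#' @param r correlation(s) in (-1, 1).
#' @param z Fisher z value(s).
#' @return transformed values.
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Run-repeatability correlation map
#'
#' Per-voxel Pearson correlation between two viewings of the same stimulus.
#' For group maps, per-subject repeatability maps are Fisher z-transformed
#' and combined with [group_fixed_effects_t()] upstream.
#'
#' @param run1,run2 voxels x frames matrices (or `voxel_image`s) of equal
#'   shape.
#' @return numeric vector of per-voxel correlations (zero-variance voxels 0,
#'   flagged via attribute `undefined`).
#' @export
run_repeatability_map <- function(run1, run2) {
  m1 <- if (inherits(run1, "voxel_image")) run1$values else as.matrix(run1)
  m2 <- if (inherits(run2, "voxel_image")) run2$values else as.matrix(run2)
  if (!all(dim(m1) == dim(m2))) stop("runs differ in shape")
  c1 <- m1 - rowMeans(m1)
  c2 <- m2 - rowMeans(m2)
  s1 <- sqrt(rowSums(c1^2)); s2 <- sqrt(rowSums(c2^2))
  r <- unname(rowSums(c1 * c2) / (s1 * s2))
  r <- pmin(pmax(r, -1), 1)
  und <- unname(which(s1 == 0 | s2 == 0))
  r[und] <- 0
  attr(r, "undefined") <- und
  r
}

#' Repeatability maps to a group fixed-effects t-map
#'
#' Convenience combiner: Fisher z-transforms each subject's repeatability
#' map, assigns unit standard errors, and applies the fixed-effects formula.
#'
#' @param r_maps list of per-subject correlation vectors.
#' @return a `stat_map` with `t` values.
#' @export
group_repeatability_t <- function(r_maps) {
  maps <- lapply(r_maps, function(r) {
    z <- fisher_z(pmin(pmax(r, -0.999999), 0.999999))
    structure(list(beta = as.matrix(z), se = as.matrix(rep(1, length(z))),
                   df = length(z) - 1, regressors = "z"),
              class = "stat_map")
  })
  group_fixed_effects_t(maps)
}
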