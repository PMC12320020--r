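# Measurement-space preprocessing chain for DOT channel data: log-mean
# ratios, noisy-channel rejection, detrend + band-pass, superficial signal
# regression, final low-pass + downsample, plus run-level data-quality
# metrics (pulse SNR, light fall-off).

#' Convert raw intensities to differential log-mean ratios
#'
#' y_m(t) = -ln( Phi_m(t) / mean_t Phi_m ), with the temporal mean taken as
#' the geometric mean so each output channel has exactly zero log-mean by
#' construction (for the small fluctuations typical of these data the
#' geometric and arithmetic means agree to second order). An intensity dip
#' maps to a positive log-ratio (increased absorption).
#'
#' @param raw a [dot_series()] with unit "intensity"; all values must be
#'   strictly positive.
#' @return a [dot_series()] with unit "log-ratio".
#' @export
logmean_ratio <- function(raw) {
  stopifnot(inherits(raw, "dot_series"))
  if (raw$unit != "intensity") stop("input must be an intensity series")
  if (any(raw$values <= 0)) stop("invalid intensity: values must be positive")
  lv <- log(raw$values)
  y <- rowMeans(lv) - lv
  dot_series(y, fs = raw$fs, unit = "log-ratio", channels = raw$channels,
             wavelength_nm = raw$wavelength_nm)
}

#' Reject noisy channels by temporal standard deviation
#'
#' A channel is kept when its temporal standard deviation (in natural-log
#' ratio units, so 0.075 is roughly a 7.5% intensity fluctuation) does not
#' exceed the threshold. The run-level retention fraction is reported, and a
#' subject-exclusion flag is raised when retention falls below
#' `retention_min`.
#'
#' @param y a [dot_series()] of log-ratios with at least 2 frames.
#' @param threshold rejection threshold on the temporal SD (default 0.075).
#' @param retention_min retention fraction below which the run flags its
#'   subject for exclusion (default 0.80).
#' @return object of class `channel_mask`: list with logical `keep`, `sd`
#'   (per-channel temporal SD), `retention`, `exclude_subject`, `threshold`.
#' @export
reject_noisy_channels <- function(y, threshold = 0.075, retention_min = 0.80) {
  stopifnot(inherits(y, "dot_series"))
  if (ncol(y$values) < 2) stop("at least 2 frames are required")
  sds <- apply(y$values, 1, stats::sd)
  keep <- sds <= threshold
  retention <- mean(keep)
  structure(list(keep = keep, sd = sds, retention = retention,
                 exclude_subject = retention < retention_min,
                 threshold = threshold),
            class = "channel_mask")
}

#' @export
print.channel_mask <- function(x, ...) {
  cat(sprintf("<channel_mask> %d/%d channels kept (retention %.1f%%)%s\n",
              sum(x$keep), length(x$keep), 100 * x$retention,
              if (x$exclude_subject) " -- SUBJECT FLAGGED FOR EXCLUSION" else ""))
  invisible(x)
}

# steady-state initial filter state for a step of unit amplitude (the
# standard construction used by zero-phase filtering: solving
# (I - A^T) z = B for the direct-form-II-transposed companion system)
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1
  b <- c(b, rep(0, m + 1 - length(b)))
  a <- c(a, rep(0, m + 1 - length(a)))
  comp <- rbind(-a[-1] / a[1],
                cbind(diag(1, m - 1), rep(0, m - 1)))
  solve(diag(m) - t(comp), b[-1] - a[-1] * b[1])
}

# direct-form-II-transposed IIR filter, vectorized over channel rows;
# zi is the per-unit initial state, scaled by each row's first sample
df2t_filter <- function(b, a, X, zi) {
  m <- length(zi)
  n <- ncol(X)
  Y <- matrix(0, nrow(X), n)
  Z <- outer(X[, 1], zi)                   # rows x state
  for (t in seq_len(n)) {
    x <- X[, t]
    y <- b[1] * x + Z[, 1]
    for (k in seq_len(m - 1))
      Z[, k] <- b[k + 1] * x - a[k + 1] * y + Z[, k + 1]
    Z[, m] <- b[m + 1] * x - a[m + 1] * y
    Y[, t] <- y
  }
  Y
}

# zero-phase 3rd-order Butterworth applied forward-backward with
# odd-reflection edge padding and steady-state initial conditions, so
# constants and slow trends do not leave edge transients
butter_filtfilt <- function(values, fs, cutoff_hz, type, order = 3) {
  w <- cutoff_hz / (fs / 2)
  if (any(w >= 1)) stop("filter-design error: cutoff at or above Nyquist")
  if (any(w <= 0)) stop("filter-design error: cutoff must be positive")
  bf <- signal::butter(order, w, type = type)
  b <- unclass(bf$b); a <- unclass(bf$a)
  zi <- lfilter_zi(b, a)
  n <- ncol(values)
  p <- min(n - 1, 3 * (max(length(a), length(b)) - 1) * 4)
  # odd reflection about the end points
  left <- 2 * values[, 1] - values[, (p + 1):2, drop = FALSE]
  right <- 2 * values[, n] - values[, (n - 1):(n - p), drop = FALSE]
  ext <- cbind(left, values, right)
  Y <- df2t_filter(b, a, ext, zi)
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  Y <- df2t_filter(b, a, Y, zi)
  Y <- Y[, rev(seq_len(ncol(Y))), drop = FALSE]
  Y[, p + seq_len(n), drop = FALSE]
}

#' Detrend and band-pass filter a channel series
#'
#' Linear detrend per channel (which also removes DC), then zero-phase
#' 3rd-order Butterworth high-pass and low-pass filters applied
#' forward-backward.
#'
#' @param y a [dot_series()].
#' @param detrend remove per-channel linear trend first (default TRUE).
#' @param hp_hz high-pass cutoff in Hz (default 0.02).
#' @param lp_hz low-pass cutoff in Hz (default 1.0); must be below Nyquist.
#' @return a filtered [dot_series()].
#' @export
temporal_filter <- function(y, detrend = TRUE, hp_hz = 0.02, lp_hz = 1.0) {
  stopifnot(inherits(y, "dot_series"))
  v <- y$values
  if (detrend) {
    tt <- seq_len(ncol(v))
    X <- cbind(1, tt)
    v <- v - t(X %*% qr.solve(X, t(v)))
  }
  v <- butter_filtfilt(v, y$fs, hp_hz, "high")
  v <- butter_filtfilt(v, y$fs, lp_hz, "low")
  dot_series(v, fs = y$fs, unit = y$unit, channels = y$channels,
             wavelength_nm = y$wavelength_nm)
}

#' Superficial signal regression
#'
#' Scalp haemodynamics dominate the shortest channels, so the mean of the
#' first-nearest-neighbour (nn1) channels is used as a global superficial
#' regressor g(t): each channel's least-squares projection onto g is
#' subtracted, leaving every output channel orthogonal to g.
#'
#' @param y a [dot_series()] whose `channels` table carries `nn_class`.
#' @param channels optional `channel_set` overriding `y$channels`.
#' @return a [dot_series()] with the superficial component removed; the
#'   regressor is attached as attribute `"regressor"`. If the nn1 mean is
#'   identically zero the input is returned unchanged with a warning.
#' @export
superficial_signal_regression <- function(y, channels = NULL) {
  stopifnot(inherits(y, "dot_series"))
  ch <- if (is.null(channels)) y$channels else channels
  if (is.null(ch) || !("nn_class" %in% names(ch)))
    stop("missing regressor: channel table with nn_class required")
  nn1 <- which(ch$nn_class == 1)
  if (length(nn1) == 0) stop("missing regressor: no first-nearest-neighbour channels")
  g <- colMeans(y$values[nn1, , drop = FALSE])
  gc <- g - mean(g)                 # slope fitted with an intercept
  gg <- sum(gc^2)
  if (gg == 0) {
    warning("superficial regressor is constant; data unchanged")
    return(y)
  }
  beta <- as.vector(y$values %*% gc) / gg
  out <- y$values - outer(beta, gc)
  res <- dot_series(out, fs = y$fs, unit = y$unit, channels = y$channels,
                    wavelength_nm = y$wavelength_nm)
  attr(res, "regressor") <- g
  res
}

#' Final low-pass and downsample
#'
#' Zero-phase 3rd-order Butterworth low-pass (anti-alias), then resampling to
#' the output rate by interpolation onto a uniform time base starting at the
#' first input frame. Output length is floor(duration * fs_out).
#'
#' @param y a [dot_series()].
#' @param lp_hz anti-alias low-pass cutoff (default 0.2).
#' @param fs_out output frame rate in Hz (default 1); must not exceed the
#'   input rate.
#' @return a [dot_series()] at `fs_out`.
#' @export
final_filter_downsample <- function(y, lp_hz = 0.2, fs_out = 1.0) {
  stopifnot(inherits(y, "dot_series"))
  if (fs_out > y$fs) stop("invalid resample: fs_out exceeds the input rate")
  v <- butter_filtfilt(y$values, y$fs, lp_hz, "low")
  n_in <- ncol(v)
  t_in <- (seq_len(n_in) - 1) / y$fs
  n_out <- floor(n_in / y$fs * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  out <- t(apply(v, 1, function(r) stats::approx(t_in, r, xout = t_out,
                                                 rule = 2)$y))
  dot_series(out, fs = fs_out, unit = y$unit, channels = y$channels,
             wavelength_nm = y$wavelength_nm)
}

#' Full measurement-space preprocessing chain
#'
#' Convenience wrapper running the standard chain on a raw intensity series:
#' log-mean ratios, noisy-channel rejection, detrend + 0.02-1 Hz band-pass,
#' superficial signal regression, 0.2 Hz low-pass and downsampling to 1 Hz.
#' Rejected channels are dropped from the output.
#'
#' @param raw a [dot_series()] of raw intensities (or log-ratios, in which
#'   case the conversion step is skipped).
#' @param sd_threshold noisy-channel threshold (see
#'   [reject_noisy_channels()]).
#' @param hp_hz,lp_hz band-pass cutoffs for [temporal_filter()].
#' @param ssr apply superficial signal regression (default TRUE).
#' @param final_lp_hz,fs_out final low-pass and output rate.
#' @return list with `series` (the processed [dot_series()]), `mask` (the
#'   [reject_noisy_channels()] result), `channels` (retained channel rows).
#' @export
preprocess_run <- function(raw, sd_threshold = 0.075, hp_hz = 0.02,
                           lp_hz = 1.0, ssr = TRUE, final_lp_hz = 0.2,
                           fs_out = 1.0) {
  y <- if (raw$unit == "intensity") logmean_ratio(raw) else raw
  mask <- reject_noisy_channels(y, threshold = sd_threshold)
  ch <- y$channels
  if (!is.null(ch)) ch <- ch[mask$keep, , drop = FALSE]
  y <- dot_series(y$values[mask$keep, , drop = FALSE], fs = y$fs,
                  unit = "log-ratio", channels = ch,
                  wavelength_nm = y$wavelength_nm)
  y <- temporal_filter(y, hp_hz = hp_hz, lp_hz = lp_hz)
  if (ssr) y <- superficial_signal_regression(y)
  y <- final_filter_downsample(y, lp_hz = final_lp_hz, fs_out = fs_out)
  list(series = y, mask = mask, channels = ch)
}

#' Band-limited pulse signal-to-noise ratio per channel
#'
#' Cardiac pulsation shows as a spectral peak near 1 Hz; its visibility is a
#' standard optode-coupling metric. Per channel this returns
#' 10*log10( P(band) / (median flanking PSD x band width) ), where P(band) is
#' the total periodogram power in `band` and the flanking bands (default
#' 0.25-0.5 and 2-3 Hz) estimate the background level.
#'
#' @param y a [dot_series()] sampled above 4 Hz, at least 60 s long.
#' @param band cardiac band in Hz (default c(0.5, 2)).
#' @param flank_bands list of two c(lo, hi) flanking bands.
#' @return numeric vector of per-channel SNRs in dB.
#' @export
pulse_snr <- function(y, band = c(0.5, 2),
                      flank_bands = list(c(0.25, 0.5), c(2, 3))) {
  stopifnot(inherits(y, "dot_series"))
  if (y$fs <= 4) stop("insufficient data: frame rate must exceed 4 Hz")
  n <- ncol(y$values)
  if (n / y$fs < 60) stop("insufficient data: run must be at least 60 s")
  freq <- seq_len(floor(n / 2)) * y$fs / n
  in_band <- freq >= band[1] & freq < band[2]
  in_flank <- Reduce(`|`, lapply(flank_bands, function(b)
    freq >= b[1] & freq < b[2]))
  bw <- band[2] - band[1]
  df <- y$fs / n
  apply(y$values, 1, function(v) {
    p <- Mod(stats::fft(v - mean(v))[seq_len(floor(n / 2)) + 1])^2 / n
    sig <- sum(p[in_band])
    floor_psd <- stats::median(p[in_flank])
    10 * log10(sig / (floor_psd * bw / df))
  })
}

#' Light fall-off curve
#'
#' Per-channel temporal-mean intensity keyed by source-detector separation;
#' light decays log-linearly with distance, and the fitted decade slope and
#' the dynamic range (max/min mean intensity) summarize detector performance.
#'
#' @param raw a [dot_series()] of raw intensities with a channel table.
#' @param by_panel also summarize per panel if the channel table carries a
#'   `panel` column.
#' @return list with `table` (separation_mm, nn_class, mean_intensity, panel),
#'   `slope_per_mm` (log10-intensity per mm), `dynamic_range`.
#' @export
light_falloff <- function(raw, by_panel = FALSE) {
  stopifnot(inherits(raw, "dot_series"))
  if (raw$unit != "intensity") stop("light fall-off requires raw intensities")
  ch <- raw$channels
  if (is.null(ch)) stop("a channel table is required")
  mi <- rowMeans(raw$values)
  tab <- data.frame(separation_mm = ch$separation_mm,
                    nn_class = ch$nn_class,
                    mean_intensity = mi)
  if (by_panel && "panel" %in% names(ch)) tab$panel <- ch$panel
  fit <- stats::lm(log10(mean_intensity) ~ separation_mm, data = tab)
  list(table = tab,
       slope_per_mm = unname(stats::coef(fit)[2]),
       dynamic_range = max(mi) / min(mi))
}
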