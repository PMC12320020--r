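# log-mean ratios, channel rejection, filtering, SSR, downsampling, QC metrics

make_series <- function(v, fs = 7.8, unit = "log-ratio", channels = NULL) {
  dot_series(matrix(v, nrow = 1), fs = fs, unit = unit, channels = channels)
}

test_that("log-mean ratio conversion inverts an exponential attenuation model", {
  fs <- 7.8
  n <- 400
  # constant channel -> zero
  const <- dot_series(matrix(2.5, 3, n), fs, unit = "intensity")
  expect_true(all(logmean_ratio(const)$values == 0))
  # Phi = Phi0 exp(-s) with zero-mean s -> s recovered exactly
  set.seed(1)
  u <- rnorm(n, sd = 0.05)
  s <- u - mean(u)
  phi <- 3e-4 * exp(-s)
  y <- logmean_ratio(dot_series(matrix(phi, 1), fs, unit = "intensity"))
  expect_equal(y$values[1, ], s, tolerance = 1e-12)
  # 10% intensity dip -> +0.105 log-ratio at the dip
  phi2 <- rep(1, n); phi2[200] <- 0.9
  y2 <- logmean_ratio(dot_series(matrix(phi2, 1), fs, unit = "intensity"))
  expect_equal(y2$values[1, 200], -log(0.9), tolerance = 1e-2)
  expect_error(logmean_ratio(dot_series(matrix(c(1, -1, 1), 1), fs,
                                        unit = "intensity")),
               "positive")
  # every output channel has zero log-mean
  ses <- default_session()
  lm <- logmean_ratio(ses$raw[["830"]])
  expect_lt(max(abs(rowMeans(lm$values))), 1e-12)
})

test_that("channel rejection applies the 7.5% threshold and flags low retention", {
  fs <- 7.8; n <- 500
  set.seed(2)
  v <- rbind(rnorm(n, sd = 0.10), rnorm(n, sd = 0.05), rep(0, n))
  y <- dot_series(v, fs)
  m <- reject_noisy_channels(y)
  expect_false(m$keep[1])   # SD 0.10 > 0.075 rejected
  expect_true(m$keep[2])    # SD 0.05 kept
  expect_true(m$keep[3])    # zero variance kept
  # 100 channels, 30 planted above threshold -> retention 0.70, flagged
  v100 <- matrix(rnorm(100 * n, sd = 0.01), 100, n)
  v100[1:30, ] <- matrix(rnorm(30 * n, sd = 0.2), 30, n)
  m100 <- reject_noisy_channels(dot_series(v100, fs))
  expect_equal(m100$retention, 0.70)
  expect_true(m100$exclude_subject)
  # retained count matches a brute-force per-channel SD computation
  brute <- sum(apply(v100, 1, sd) <= 0.075)
  expect_equal(sum(m100$keep), brute)
})

test_that("band-pass filter attenuates out-of-band sinusoids and passes in-band ones", {
  fs <- 7.8
  tt <- seq(0, 600, by = 1 / fs)
  gain <- function(f_hz) {
    y <- make_series(sin(2 * pi * f_hz * tt), fs)
    out <- temporal_filter(y)$values[1, ]
    # steady-state amplitude away from filter edges
    core <- seq(round(length(tt) * 0.3), round(length(tt) * 0.7))
    max(abs(out[core]))
  }
  expect_lt(gain(0.005), 0.1)              # below 0.02 Hz: > 10x attenuation
  expect_gt(gain(0.1), 0.9)                # passband within 10%
  expect_lt(gain(2), 0.1)                  # above 1 Hz: > 10x attenuation
  # constant input -> ~0 after detrend + high-pass
  cst <- temporal_filter(make_series(rep(4, length(tt)), fs))
  expect_lt(max(abs(cst$values)), 1e-8)
  expect_error(temporal_filter(make_series(rnorm(100), fs), lp_hz = 5),
               "Nyquist")
})

test_that("superficial signal regression annihilates nn1-proportional signal exactly", {
  fs <- 7.8; n <- 800
  set.seed(3)
  ch <- data.frame(nn_class = c(1, 1, 2, 3, 4))
  g <- sin(2 * pi * 0.09 * (1:n) / fs)     # zero-mean global signal
  g <- g - mean(g)
  coef <- c(1, 1, 0.6, 0.3, 0.2)
  y <- dot_series(outer(coef, g), fs, channels = ch)
  out <- superficial_signal_regression(y)
  expect_lt(max(abs(out$values)), 1e-10)
  # orthogonal private signal survives untouched
  s_priv <- sin(2 * pi * 0.25 * (1:n) / fs)
  s_priv <- s_priv - mean(s_priv)
  s_priv <- s_priv - g * sum(s_priv * g) / sum(g^2)   # orthogonalize
  v <- outer(coef, g)
  v[4, ] <- v[4, ] + s_priv
  out2 <- superficial_signal_regression(dot_series(v, fs, channels = ch))
  expect_equal(out2$values[4, ], s_priv, tolerance = 1e-8)
  # post-hoc correlation with the regressor is numerically zero
  ses <- default_session()
  res <- superficial_signal_regression(ses$y[["830"]])
  expect_lt(max(abs(cor(t(res$values), attr(res, "regressor")))), 1e-10)
  # degenerate regressor: warning, unchanged data
  zero <- dot_series(matrix(0, 3, n), fs,
                     channels = data.frame(nn_class = c(1, 2, 3)))
  expect_warning(unchanged <- superficial_signal_regression(zero), "constant")
  expect_equal(unchanged$values, zero$values)
  expect_error(superficial_signal_regression(
    dot_series(matrix(0, 2, n), fs, channels = data.frame(nn_class = c(2, 3)))),
    "first-nearest")
})

test_that("final low-pass + downsample yields floor(duration*fs_out) frames and preserves slow signals", {
  fs <- 7.8
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)   # exactly 600 s of samples
  y <- make_series(sin(2 * pi * 0.05 * tt), fs)
  out <- final_filter_downsample(y)
  expect_equal(ncol(out$values), 600)
  expect_equal(out$fs, 1)
  core <- 150:450
  expect_gt(max(abs(out$values[1, core])), 0.9)   # amplitude within 10%
  # constant zero stays zero
  z <- final_filter_downsample(make_series(rep(0, length(tt)), fs))
  expect_true(all(z$values == 0))
  expect_error(final_filter_downsample(y, fs_out = 20), "invalid resample")
})

test_that("the chain is nearly idempotent for content inside the passband", {
  # channels carry mutually orthogonal mid-passband sinusoids (disjoint DFT
  # bins, 0.056-0.068 Hz) plus a shared superficial-like component; repeated
  # filtering is then near-identity and the re-estimated SSR slopes are the
  # only source of change (finite-window estimation error, ~1%)
  fs <- 7.8
  n <- 16384
  tt <- (seq_len(n) - 1) / fs
  T_s <- n / fs
  nch <- 12
  ch <- data.frame(nn_class = rep(c(1, 2, 3), each = 4))
  k0 <- ceiling(0.056 * T_s)
  ks <- k0 + seq_len(nch + 1) - 1
  shared <- sin(2 * pi * ks[nch + 1] / T_s * tt)
  own <- t(sapply(seq_len(nch), function(i) 0.15 * sin(2 * pi * ks[i] / T_s * tt)))
  y <- dot_series(own + outer(rep(c(1, 0.6, 0.4), each = 4), shared), fs,
                  channels = ch)
  chain <- function(z) {
    z <- temporal_filter(z, hp_hz = 0.02, lp_hz = 1.0)
    z <- superficial_signal_regression(z)
    dot_series(vhdot:::butter_filtfilt(z$values, z$fs, 0.2, "low"), z$fs,
               channels = z$channels)
  }
  p1 <- chain(y)
  p2 <- chain(p1)
  rms <- function(m) sqrt(mean(m^2))
  core <- 1000:(n - 1000)
  expect_lt(rms(p2$values[, core] - p1$values[, core]) /
              rms(p1$values[, core]), 0.02)
})
test_that("pulse SNR metric behaves like a band-power ratio", {
  fs <- 7.8
  tt <- seq(0, 300 - 1 / fs, by = 1 / fs)
  set.seed(4)
  noise <- rnorm(length(tt), sd = 0.02)
  snr_of <- function(a) {
    y <- make_series(a * sin(2 * pi * 1 * tt) + noise, fs)
    pulse_snr(y)
  }
  expect_gt(snr_of(0.05), 10)                       # clear 1 Hz peak
  expect_lt(abs(pulse_snr(make_series(noise, fs))), 2)  # white noise ~ 0 dB
  expect_equal(snr_of(0.4) - snr_of(0.2), 6, tolerance = 1)  # +6 dB per doubling
  expect_error(pulse_snr(make_series(noise, fs = 3)), "frame rate")
  expect_error(pulse_snr(make_series(rnorm(100), fs)), "60 s")
})

test_that("light fall-off recovers a planted log-linear decay", {
  ses <- default_session()
  lf <- light_falloff(ses$raw[["830"]])
  # generator decays one decade per 5 mm
  expect_equal(lf$slope_per_mm, -1 / 5, tolerance = 0.02)
  expect_gt(lf$dynamic_range, 1e4)
  # constant intensities -> zero slope
  ch <- ses$raw[["830"]]$channels
  const <- dot_series(matrix(1, nrow(ch), 50), 7.8, unit = "intensity",
                      channels = ch)
  expect_equal(light_falloff(const)$slope_per_mm, 0, tolerance = 1e-12)
  expect_error(light_falloff(ses$y[["830"]]), "raw intensities")
})
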