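# stimulus feature regressors, correlation maps, repeatability

test_that("luminance trace averages grayscale intensity with standard luma weights", {
  black <- replicate(10, matrix(0, 4, 4), simplify = FALSE)
  expect_true(all(luminance_trace(black, fps = 10)$values == 0))
  # alternating black/white at 2 fps, output 1 Hz = mean of each pair
  frames <- rep(list(matrix(0, 2, 2), matrix(1, 2, 2)), 5)
  lum <- luminance_trace(frames, fps = 2)
  expect_equal(lum$values, rep(0.5, 5))
  # RGB hand oracle
  rgb <- array(0, c(2, 2, 3))
  rgb[, , 1] <- 0.2; rgb[, , 2] <- 0.5; rgb[, , 3] <- 0.9
  lum_rgb <- luminance_trace(list(rgb), fps = 1)
  expect_equal(lum_rgb$values, 0.299 * 0.2 + 0.587 * 0.5 + 0.114 * 0.9,
               tolerance = 1e-12)
  expect_error(luminance_trace(list(), fps = 1), "no frames")
})

test_that("audio envelope tracks amplitude modulation and the log transform", {
  fs_a <- 20000
  tt <- seq(0, 10 - 1 / fs_a, by = 1 / fs_a)
  modulator <- 1 + 0.9 * sin(2 * pi * 0.2 * tt)
  wave <- modulator * sin(2 * pi * 1000 * tt)
  env <- audio_envelope(wave, fs_a)
  mod_1hz <- vapply(1:10, function(k)
    mean(modulator[((k - 1) * fs_a + 1):(k * fs_a)]), numeric(1))
  expect_gt(cor(env$values, log10(mod_1hz)), 0.9)
  # silence: constant floor, flagged
  sil <- audio_envelope(rep(0, fs_a * 2), fs_a)
  expect_true(attr(sil, "silent"))
  expect_equal(length(unique(sil$values)), 1)
  # doubling a broadband signal raises every band's log power by
  # 20*log10(2) ~ 6 dB, hence the band-mean too
  set.seed(30)
  broad <- rnorm(fs_a * 4)
  eb1 <- audio_envelope(broad, fs_a)
  eb2 <- audio_envelope(2 * broad, fs_a)
  expect_equal(mean(eb2$values) - mean(eb1$values), 20 * log10(2),
               tolerance = 0.02)
})

test_that("rating consensus is a majority vote, permutation-invariant, with ties flagged", {
  r <- rbind(c(1, 1, 0, 0, 1),
             c(1, 0, 0, 1, 1),
             c(0, 1, 0, 1, 1))
  cons <- binary_feature_consensus(r)
  expect_equal(cons$values, c(1, 1, 0, 1, 1))
  expect_length(attr(cons, "reevaluate"), 0)
  # unanimous ratings pass through
  u <- rbind(c(1, 0, 1), c(1, 0, 1))
  expect_equal(binary_feature_consensus(u)$values, c(1, 0, 1))
  # 2 raters disagreeing on 5 bins -> 5 re-evaluation flags
  a <- c(1, 0, 1, 0, 1, 0, 0, 1)
  b <- c(0, 1, 0, 1, 0, 0, 0, 1)
  cons2 <- binary_feature_consensus(rbind(a, b))
  expect_length(attr(cons2, "reevaluate"), 5)
  # rater order does not matter
  set.seed(16)
  r3 <- matrix(rbinom(3 * 30, 1, 0.5), 3, 30)
  expect_equal(binary_feature_consensus(r3)$values,
               binary_feature_consensus(r3[c(3, 1, 2), ])$values)
  expect_error(binary_feature_consensus(matrix(2, 1, 3)), "binary")
})

test_that("the regressor pipeline convolves with the HRF and band-passes", {
  # unit impulse -> band-passed HRF shape
  x <- c(rep(0, 10), 1, rep(0, 289))
  out <- regressor_pipeline(x)
  kern <- canonical_hrf(0:32)
  ref <- numeric(300); ref[11:43] <- kern
  ref_bp <- as.vector(vhdot:::butter_filtfilt(
    vhdot:::butter_filtfilt(matrix(ref, 1), 1, 0.02, "high"), 1, 0.2, "low"))
  expect_gt(cor(out$values, ref_bp), 0.999)
  expect_equal(mean(out$values), 0, tolerance = 1e-12)
  # constant trace ~ 0 after band-pass
  cst <- regressor_pipeline(rep(3, 300))
  expect_lt(max(abs(cst$values)), 1e-6)
  # commutes with amplitude scaling
  set.seed(17)
  tr <- runif(300)
  expect_equal(regressor_pipeline(5 * tr)$values,
               5 * regressor_pipeline(tr)$values, tolerance = 1e-9)
  # a slow boxcar train keeps its fundamental in the passband
  box <- rep(rep(c(1, 0), each = 15), 10)
  out_box <- regressor_pipeline(box)
  sp <- Mod(fft(out_box$values))^2
  f <- (seq_along(sp) - 1) / length(sp)
  fund <- which.min(abs(f - 1 / 30))
  expect_gt(sp[fund], 0.5 * max(sp[2:(length(sp) / 2)]))
  expect_error(regressor_pipeline(rep(1, 10)), "shorter")
})

test_that("feature correlation maps are exact for planted signals", {
  set.seed(18)
  reg <- rnorm(200)
  m <- rbind(reg, -reg, rnorm(200), rep(0, 200))
  r <- feature_correlation_map(reg, m)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(r[2], -1, tolerance = 1e-12)
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(r[4], 0)
  expect_equal(attr(r, "undefined"), 4L)
})

test_that("a planted movie feature drives its ROI above the background", {
  mov <- make_movie_session(session_spec(), shared_snr = 2, duration_s = 200,
                           seed = 21)
  op <- inverse_operator(mov$A[["830"]])
  x2 <- reconstruct(op, final_filter_downsample(temporal_filter(mov$run2[["830"]])))
  speech <- mov$truth$features$speech$values[seq_len(ncol(x2$values))]
  r <- feature_correlation_map(speech, x2)
  roi <- mov$truth$rois[[2]]$voxels     # speech-driven ROI
  brain <- which(voxel_layers(mov$phantom) == "brain")
  expect_gt(median(r[roi]), median(r[setdiff(brain, roi)]))
})

test_that("repeatability maps and Fisher transform behave as correlations", {
  set.seed(19)
  m <- matrix(rnorm(50 * 100), 50, 100)
  r_same <- run_repeatability_map(m, m)
  expect_equal(as.numeric(r_same), rep(1, 50), tolerance = 1e-12)
  # independent noise: distribution centred at zero
  r_ind <- run_repeatability_map(matrix(rnorm(1000 * 80), 1000, 80),
                                 matrix(rnorm(1000 * 80), 1000, 80))
  expect_lt(abs(mean(r_ind)), 0.02)
  expect_true(all(abs(r_ind) <= 1))
  # shared component confined to an ROI
  shared <- matrix(rnorm(30 * 80), 30, 80)
  a <- rbind(shared + 0.8 * matrix(rnorm(30 * 80), 30, 80),
             matrix(rnorm(70 * 80), 70, 80))
  b <- rbind(shared + 0.8 * matrix(rnorm(30 * 80), 30, 80),
             matrix(rnorm(70 * 80), 70, 80))
  r_ab <- run_repeatability_map(a, b)
  expect_gt(min(r_ab[1:30]), max(0, quantile(r_ab[31:100], 0.5)))
  # Fisher z round trip
  rr <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(rr)), rr, tolerance = 1e-12)
  # group combiner returns finite t with the right sign pattern
  gt <- group_repeatability_t(list(r_ab, r_ab))
  expect_true(all(is.finite(gt$t)))
  expect_gt(mean(gt$t[1:30]), mean(gt$t[31:100]))
})
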