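# PSF image-quality metrics and the benchmarking study machinery

delta_image <- function(ph, center) {
  pos <- voxel_centers(ph)
  v <- numeric(prod(ph$dims))
  v[which.min(rowSums(sweep(pos, 2, center)^2))] <- 1
  voxel_image(v, ph)
}

test_that("equiv-sphere FWHM of a single-voxel delta is the one-voxel sphere diameter", {
  ph <- slab_phantom(c(20, 20, 12), voxel_mm = 2)
  img <- delta_image(ph, c(10, 10, 7))
  expect_equal(psf_fwhm(img), (6 * 8 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(psf_fwhm(img), 2.48, tolerance = 1e-2)
  expect_error(psf_fwhm(voxel_image(rep(0, prod(ph$dims)), ph)), "degenerate")
})

test_that("FWHM of an isotropic Gaussian matches 2.355 sigma and ignores amplitude", {
  ph <- slab_phantom(c(60, 60, 40), voxel_mm = 1)
  pos <- voxel_centers(ph)
  sigma <- 5
  g <- exp(-rowSums(sweep(pos, 2, c(30, 30, 20))^2) / (2 * sigma^2))
  img <- voxel_image(g, ph)
  expect_equal(psf_fwhm(img), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 1 / (2.355 * sigma))      # within one voxel
  # amplitude invariance
  expect_equal(psf_fwhm(voxel_image(7.3 * g, ph)), psf_fwhm(img))
})

test_that("localization error is the intensity-weighted centroid offset", {
  ph <- slab_phantom(c(20, 20, 12), voxel_mm = 2)
  img <- delta_image(ph, c(11, 11, 7))
  # delta at its own position: zero error (within half a voxel)
  tp <- voxel_centers(ph)[which.max(img$values[, 1]), ]
  expect_lt(psf_localization_error(img, tp), 1e-9)
  # delta 4 mm from the queried position
  expect_equal(psf_localization_error(img, tp + c(4, 0, 0)), 4)
  # 3-voxel hand-built PSF vs hand-computed weighted mean
  v <- numeric(prod(ph$dims))
  idx <- c(voxel_index(ph, 3, 5, 3), voxel_index(ph, 4, 5, 3),
           voxel_index(ph, 5, 5, 3))
  v[idx] <- c(2, 4, 2)
  img3 <- voxel_image(v, ph)
  pos <- voxel_centers(ph)[idx, ]
  cen <- colSums(pos * c(2, 4, 2)) / 8
  tp2 <- c(0, 0, 0)
  expect_equal(psf_localization_error(img3, tp2),
               sqrt(sum((cen - tp2)^2)), tolerance = 1e-12)
})

test_that("effective resolution is the covering-sphere diameter and bounds localization error", {
  ph <- slab_phantom(c(40, 40, 40), voxel_mm = 2)
  half_diag <- sqrt(3)
  img <- delta_image(ph, c(21, 21, 21))
  tp <- voxel_centers(ph)[which.max(img$values[, 1]), ]
  # delta exactly at true position: one voxel diagonal
  expect_equal(psf_effective_resolution(img, tp), 2 * half_diag)
  # half-max region = 10 mm ball centred at true position -> ~20 mm
  pos <- voxel_centers(ph)
  ball <- as.numeric(sqrt(rowSums(sweep(pos, 2, tp)^2)) <= 10)
  # analytic oracle: ball radius + covering half-diagonal, doubled
  expect_equal(psf_effective_resolution(voxel_image(ball, ph), tp),
               20 + 2 * half_diag, tolerance = 2 / 20)
  # shifted ball: centre 5 mm off -> covering radius 15 + half-diagonal
  tp_off <- tp - c(5, 0, 0)
  er <- psf_effective_resolution(voxel_image(ball, ph), tp_off)
  expect_equal(er, 30 + 2 * half_diag, tolerance = 2 / 30)
  expect_gte(er, psf_localization_error(voxel_image(ball, ph), tp_off))
  # property: effective resolution >= localization error on random blobs
  set.seed(8)
  for (k in 1:10) {
    v <- pmax(rnorm(prod(ph$dims)), 0)
    v[sample(length(v), 5)] <- 5 + runif(5)
    img_r <- voxel_image(v, ph)
    tpr <- pos[sample(nrow(pos), 1), ]
    expect_gte(psf_effective_resolution(img_r, tpr),
               psf_localization_error(img_r, tpr))
  }
})

test_that("PSF SNR matches a hand-computed ratio and scales inversely with noise", {
  ph <- slab_phantom(c(20, 20, 12), voxel_mm = 2)
  v <- numeric(prod(ph$dims))
  idx <- c(voxel_index(ph, 3, 3, 2), voxel_index(ph, 4, 3, 2))
  v[idx] <- c(10, 8)
  img <- voxel_image(v, ph)
  set.seed(3)
  noise <- matrix(rnorm(prod(ph$dims) * 40), ncol = 40)
  want <- mean(c(10, 8)) / mean(apply(noise[idx, ], 1, sd))
  expect_equal(psf_snr(img, noise), want, tolerance = 1e-12)
  expect_equal(psf_snr(img, 2 * noise), want / 2, tolerance = 1e-12)
  expect_error(psf_snr(img, noise[, 1:5]), "10")
  expect_equal(psf_snr(img, matrix(0, prod(ph$dims), 12)), Inf)
})

test_that("identity operator returns a single-voxel delta PSF", {
  # square identity sensitivity, no regularization: PSF is the seed itself
  n <- 27
  ph <- slab_phantom(c(6, 6, 6), voxel_mm = 2)
  A <- structure(list(A = diag(n),
                      channels = data.frame(separation_mm = rep(10, n)),
                      phantom = ph, wavelength = 830),
                 class = "sensitivity_matrix")
  op <- inverse_operator(A, lambda1 = 0, lambda2 = 0)
  res <- simulate_psf(A, op, seed_voxel = 14, amplitude = 2)
  x <- res$psf$values[, 1]
  expect_equal(which.max(x), 14)
  expect_equal(x[14], 2, tolerance = 1e-8)
  expect_lt(max(abs(x[-14])), 1e-8)
  # noiseless PSFs are bit-for-bit repeatable and linear in amplitude
  res2 <- simulate_psf(A, op, seed_voxel = 14, amplitude = 2)
  expect_identical(res$psf$values, res2$psf$values)
  res4 <- simulate_psf(A, op, seed_voxel = 14, amplitude = 4)
  expect_equal(res4$psf$values, 2 * res$psf$values)
  expect_error(simulate_psf(A, op, seed_voxel = n + 1), "outside")
})

test_that("depth profile medians match a brute-force percentile oracle", {
  set.seed(5)
  rep1 <- data.frame(seed_voxel = 1:60, x = 0, y = 0,
                     depth_mm = runif(60, 5, 25),
                     fwhm_mm = runif(60, 5, 20),
                     loc_err_mm = runif(60, 0, 10),
                     eff_res_mm = runif(60, 10, 40),
                     snr = runif(60, 0.1, 3))
  class(rep1) <- c("psf_report", "data.frame")
  prof <- depth_profile(rep1, bin_mm = 5)
  for (b in seq_len(nrow(prof))) {
    lo <- prof$depth_lo[b]; hi <- prof$depth_hi[b]
    sel <- rep1$depth_mm >= lo &
      (if (b == nrow(prof)) rep1$depth_mm <= hi else rep1$depth_mm < hi)
    expect_equal(prof$fwhm_mm[b], median(rep1$fwhm_mm[sel]))
    expect_equal(prof$snr[b], median(rep1$snr[sel]))
  }
  # identical inputs give identical tables
  prof2 <- depth_profile(list(a = rep1, b = rep1), bin_mm = 5)
  expect_equal(prof2[prof2$design == "a", -1], prof2[prof2$design == "b", -1],
               ignore_attr = TRUE)
  # empty bins warn (one warning per empty bin)
  rep_shallow <- rep1[rep1$depth_mm < 10, ]
  class(rep_shallow) <- c("psf_report", "data.frame")
  w <- capture_warnings(depth_profile(rep_shallow, bin_mm = 5))
  expect_true(all(grepl("empty depth bin", w)) && length(w) >= 1)
})

test_that("a small-scale psf_study agrees with the dense single-seed path", {
  ph <- slab_phantom(c(48, 48, 24), voxel_mm = 2)
  rep_small <- psf_study(9.75, phantom = ph, lateral_step_mm = 12,
                         lateral_margin_mm = 18, depth_band = c(5, 15),
                         n_noise = 12, rng_seed = 2, block_voxels = 1000)
  expect_s3_class(rep_small, "psf_report")
  expect_true(all(rep_small$fwhm_mm > 0))
  expect_true(all(rep_small$eff_res_mm >= rep_small$loc_err_mm))
  expect_true(all(rep_small$depth_mm >= 5 & rep_small$depth_mm <= 15))
  # dual-route check: rebuild the same design densely and compare one PSF
  ext <- ph$dims * ph$voxel_mm
  n_c <- floor(ext[1] / 9.75) + 1
  ox <- (ext[1] - (n_c - 1) * 9.75) / 2
  g <- checkerboard_grid(9.75, n_c, n_c, origin = c(ox, ox, 0))
  ch <- enumerate_channels(g, 40, wavelengths = 830)
  A <- slab_sensitivity(g, ch, ph, 830)
  op <- inverse_operator(A)
  seed <- rep_small$seed_voxel[1]
  dense <- simulate_psf(A, op, seed, amplitude = 0.01)
  expect_equal(psf_fwhm(dense$psf), rep_small$fwhm_mm[1], tolerance = 1e-8)
  expect_equal(psf_localization_error(dense$psf,
                                      voxel_centers(ph)[seed, ]),
               rep_small$loc_err_mm[1], tolerance = 1e-8)
})
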