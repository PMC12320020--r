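# Point-spread-function image-quality benchmarking of optode-array designs:
# reconstruct single-voxel perturbations across the slab and summarise each
# PSF by FWHM, localization error, effective resolution, and SNR vs depth.

#' Simulate the point-spread function of a seed voxel
#'
#' Projects a single-voxel absorption perturbation through the forward model
#' and reconstructs it (noiselessly); optionally also reconstructs a stack of
#' pure-noise measurement vectors for SNR estimation.
#'
#' @param A a [slab_sensitivity()] result.
#' @param op an [inverse_operator()] built from `A`.
#' @param seed_voxel flat voxel index of the perturbation.
#' @param amplitude perturbation amplitude (mm^-1 absorption change).
#' @param noise a [noise_model()] or NULL; when given, `n_noise_realizations`
#'   noise-only measurement vectors are reconstructed.
#' @param n_noise_realizations number of noise reconstructions (>= 10 for a
#'   usable SNR estimate).
#' @param rng_seed integer seed for the noise draws.
#' @return list with `psf` (a [voxel_image()]), `noise_images` (voxels x
#'   realizations matrix or NULL), `seed_voxel`, `true_pos` (mm).
#' @export
simulate_psf <- function(A, op, seed_voxel, amplitude = 0.01, noise = NULL,
                         n_noise_realizations = 50, rng_seed = 1) {
  stopifnot(inherits(A, "sensitivity_matrix"), inherits(op, "inverse_operator"))
  nv <- ncol(A$A)
  if (seed_voxel < 1 || seed_voxel > nv) stop("seed voxel outside the grid")
  y <- A$A[, seed_voxel] * amplitude
  psf <- reconstruct(op, matrix(y, ncol = 1))
  noise_images <- NULL
  if (!is.null(noise)) {
    sig <- noise_sigma(noise, A$channels$separation_mm)
    old <- .Random.seed_save()
    set.seed(rng_seed)
    N <- matrix(stats::rnorm(nrow(A$A) * n_noise_realizations,
                             sd = rep(sig, n_noise_realizations)),
                nrow(A$A), n_noise_realizations)
    .Random.seed_restore(old)
    ni <- reconstruct(op, N)
    noise_images <- if (inherits(ni, "voxel_image")) ni$values else ni
  }
  list(psf = psf, noise_images = noise_images, seed_voxel = seed_voxel,
       true_pos = voxel_centers(A$phantom)[seed_voxel, ])
}

# half-maximum support of a PSF: flat indices of voxels >= frac * max
psf_region <- function(psf, frac = 0.5) {
  v <- psf$values[, 1]
  mx <- max(v)
  if (mx <= 0) stop("degenerate PSF: maximum is not positive")
  which(v >= frac * mx)
}

#' PSF full width at half maximum
#'
#' The default "equiv-sphere" mode measures the volume V of the region at or
#' above 50% of the PSF maximum and reports the diameter of the sphere of
#' equal volume, (6V/pi)^(1/3); PSFs are anisotropic, so a volumetric
#' equivalent is more stable than any single profile width. "max-extent"
#' instead reports the largest centre-to-centre distance across the region
#' plus one voxel spacing.
#'
#' @param psf a [voxel_image()] with a positive maximum.
#' @param mode "equiv-sphere" (default) or "max-extent".
#' @return width in mm.
#' @export
psf_fwhm <- function(psf, mode = c("equiv-sphere", "max-extent")) {
  mode <- match.arg(mode)
  reg <- psf_region(psf)
  h <- psf$phantom$voxel_mm
  if (mode == "equiv-sphere") {
    V <- length(reg) * h^3
    (6 * V / pi)^(1 / 3)
  } else {
    pts <- voxel_centers(psf$phantom)[reg, , drop = FALSE]
    if (nrow(pts) == 1) return(h)
    max(stats::dist(pts)) + h
  }
}

#' PSF localization error
#'
#' Euclidean distance between the true perturbation position and the
#' intensity-weighted centroid of the PSF, the centroid being computed over
#' the >= 50%-of-maximum region only (full-volume centroids are dominated by
#' reconstruction ripple).
#'
#' @param psf a [voxel_image()].
#' @param true_pos length-3 position of the perturbation (mm).
#' @return distance in mm.
#' @export
psf_localization_error <- function(psf, true_pos) {
  reg <- psf_region(psf)
  pts <- voxel_centers(psf$phantom)[reg, , drop = FALSE]
  w <- psf$values[reg, 1]
  cen <- colSums(pts * w) / sum(w)
  sqrt(sum((cen - true_pos)^2))
}

#' PSF effective resolution
#'
#' Diameter of the sphere, centred on the true perturbation position, needed
#' to cover every voxel of the >= 50%-of-maximum region: twice the largest
#' covering radius (centre distance plus the voxel half-diagonal). Combines
#' blur and mislocalization into one spatial-uncertainty number and is always
#' at least the localization error.
#'
#' @inheritParams psf_localization_error
#' @return diameter in mm.
#' @export
psf_effective_resolution <- function(psf, true_pos) {
  reg <- psf_region(psf)
  pts <- voxel_centers(psf$phantom)[reg, , drop = FALSE]
  half_diag <- sqrt(3) * psf$phantom$voxel_mm / 2
  d <- sqrt(rowSums(sweep(pts, 2, true_pos)^2))
  2 * max(d + half_diag)
}

#' PSF signal-to-noise ratio
#'
#' Mean PSF value over the >= 50%-of-maximum region divided by the mean (over
#' that region) of the per-voxel standard deviation across noise-only
#' reconstructions.
#'
#' @param psf a [voxel_image()].
#' @param noise_images voxels x realizations matrix of noise-only
#'   reconstructions (>= 10 realizations).
#' @return dimensionless ratio; `Inf` if the noise SD is exactly zero.
#' @export
psf_snr <- function(psf, noise_images) {
  if (ncol(noise_images) < 10)
    stop("at least 10 noise realizations are required")
  reg <- psf_region(psf)
  sig <- mean(psf$values[reg, 1])
  sd_vox <- apply(noise_images[reg, , drop = FALSE], 1, stats::sd)
  ns <- mean(sd_vox)
  if (ns == 0) return(Inf)
  sig / ns
}

#' Benchmark one array design with a grid of PSF simulations
#'
#' Builds a checkerboard grid of the requested pitch centred over the phantom,
#' enumerates channels below the separation cutoff, assembles the slab
#' sensitivity matrix and regularized inverse, then reconstructs single-voxel
#' perturbations seeded on a lateral/depth lattice and scores each PSF with
#' the four image-quality metrics. One shared noise-reconstruction stack is
#' used for all seeds (the noise statistics do not depend on the seed).
#'
#' @param pitch_mm optode pitch of the design under test (mm).
#' @param phantom a [slab_phantom()]; default 160 x 160 x 30 mm at 2 mm.
#' @param max_separation_mm channel separation cutoff (default 40).
#' @param wavelength which wavelength's optical properties to use.
#' @param lambda1,lambda2 regularization weights (defaults 0.01 / 0.1).
#' @param noise a [noise_model()] used for the SNR stack (NULL skips SNR).
#' @param amplitude perturbation amplitude, mm^-1.
#' @param lateral_step_mm,lateral_margin_mm seed spacing and edge margin in
#'   x/y (seeds are placed on voxel centres nearest the resulting lattice).
#' @param depth_band analysis band in mm from the surface (default 5-25).
#' @param depth_step_mm seed spacing in depth.
#' @param n_noise noise realizations for SNR.
#' @param rng_seed seed for the noise stack.
#' @param fwhm_mode passed to [psf_fwhm()].
#' @param smax_scale lambda1 scaling convention, as in [inverse_operator()].
#' @param block_voxels voxel block size for the memory-blocked assembly of the
#'   Gram matrix; the full Jacobian is never held in memory at once, so the
#'   peak footprint is a few blocks of `n_channels` x `block_voxels`.
#' @return object of class `psf_report`: data.frame with one row per seed
#'   (`x`, `y`, `depth_mm`, `fwhm_mm`, `loc_err_mm`, `eff_res_mm`, `snr`) and
#'   attributes `pitch_mm`, `n_channels`.
#' @export
psf_study <- function(pitch_mm, phantom = slab_phantom(),
                      max_separation_mm = 40, wavelength = 830,
                      lambda1 = 0.01, lambda2 = 0.1,
                      noise = noise_model(), amplitude = 0.01,
                      lateral_step_mm = 16, lateral_margin_mm = 30,
                      depth_band = c(5, 25), depth_step_mm = 2,
                      n_noise = 50, rng_seed = 1,
                      fwhm_mode = "equiv-sphere",
                      smax_scale = c("eigen", "diag", "none"),
                      block_voxels = 8192) {
  smax_scale <- match.arg(smax_scale)
  ext <- phantom$dims * phantom$voxel_mm
  n_cols <- floor(ext[1] / pitch_mm) + 1
  n_rows <- floor(ext[2] / pitch_mm) + 1
  ox <- (ext[1] - (n_cols - 1) * pitch_mm) / 2
  oy <- (ext[2] - (n_rows - 1) * pitch_mm) / 2
  grid <- checkerboard_grid(pitch_mm, n_rows, n_cols, origin = c(ox, oy, 0))
  ch <- enumerate_channels(grid, max_separation_mm, wavelengths = wavelength)

  # seed lattice: voxel centres nearest a lateral grid, all depth slices in band
  near_idx <- function(targets, centers)
    unique(vapply(targets, function(t) which.min(abs(centers - t)), 1L))
  lx <- near_idx(seq(lateral_margin_mm, ext[1] - lateral_margin_mm,
                     by = lateral_step_mm), phantom$xs)
  ly <- near_idx(seq(lateral_margin_mm, ext[2] - lateral_margin_mm,
                     by = lateral_step_mm), phantom$ys)
  kz <- which(phantom$zs >= depth_band[1] & phantom$zs <= depth_band[2])
  kz <- kz[seq(1, length(kz),
               by = max(1L, round(depth_step_mm / phantom$voxel_mm)))]
  seeds <- as.vector(outer(as.vector(outer(lx, (ly - 1) * phantom$dims[1], "+")),
                           (kz - 1) * phantom$dims[1] * phantom$dims[2], "+"))

  sys <- blocked_slab_system(grid, ch, phantom, wavelength,
                             block_voxels = block_voxels)
  nv <- prod(phantom$dims)
  nch <- nrow(sys$channels)

  # pass 1: column norms of A for the spatially-variant scale L
  cs <- numeric(nv)
  for (b in sys$blocks) cs[b] <- colSums(sys$block(b)^2)
  if (max(cs) == 0) stop("singular operator: sensitivity matrix is all zero")
  L <- sqrt(cs + lambda2 * max(cs))
  Linv <- 1 / L

  # pass 2: blocked Gram matrix of the column-scaled Jacobian
  M0 <- matrix(0, nch, nch)
  for (b in sys$blocks) {
    Ab <- sys$block(b)
    Ab <- Ab * rep(Linv[b], each = nch)
    M0 <- M0 + tcrossprod(Ab)
  }
  s <- switch(smax_scale,
              eigen = largest_eigenvalue(M0),
              diag  = max(diag(M0)),
              none  = 1)
  diag(M0) <- diag(M0) + lambda1 * s
  R <- chol(M0)
  rm(M0)

  # dual-space solves for all seed PSFs and the shared noise stack
  Y <- sys$block(seeds) * amplitude           # seed columns of A
  if (!is.null(noise)) {
    sig <- noise_sigma(noise, sys$channels$separation_mm)
    old <- .Random.seed_save()
    set.seed(rng_seed)
    N <- matrix(stats::rnorm(nch * n_noise, sd = rep(sig, n_noise)),
                nch, n_noise)
    .Random.seed_restore(old)
    Y <- cbind(Y, N)
  }
  Z <- backsolve(R, forwardsolve(t(R), Y))

  # pass 3: back-projection x = diag(1/L) A~' z, blocked over voxels
  X <- matrix(0, nv, ncol(Z))
  for (b in sys$blocks) {
    Ab <- sys$block(b)
    X[b, ] <- crossprod(Ab, Z) * Linv[b]^2    # A~ = A diag(1/L), plus diag(1/L)
  }
  sd_vox <- NULL
  if (!is.null(noise)) {
    NI <- X[, length(seeds) + seq_len(n_noise), drop = FALSE]
    mu <- rowMeans(NI)
    sd_vox <- sqrt(rowSums((NI - mu)^2) / (n_noise - 1))
    X <- X[, seq_along(seeds), drop = FALSE]
  }

  pos <- voxel_centers(phantom)
  out <- data.frame(seed_voxel = seeds,
                    x = pos[seeds, 1], y = pos[seeds, 2],
                    depth_mm = pos[seeds, 3],
                    fwhm_mm = NA_real_, loc_err_mm = NA_real_,
                    eff_res_mm = NA_real_, snr = NA_real_)
  for (i in seq_along(seeds)) {
    psf <- voxel_image(X[, i], phantom)
    tp <- pos[seeds[i], ]
    out$fwhm_mm[i] <- psf_fwhm(psf, mode = fwhm_mode)
    out$loc_err_mm[i] <- psf_localization_error(psf, tp)
    out$eff_res_mm[i] <- psf_effective_resolution(psf, tp)
    if (!is.null(sd_vox)) {
      reg <- psf_region(psf)
      ns <- mean(sd_vox[reg])
      out$snr[i] <- if (ns == 0) Inf else mean(psf$values[reg, 1]) / ns
    }
  }
  class(out) <- c("psf_report", "data.frame")
  attr(out, "pitch_mm") <- pitch_mm
  attr(out, "n_channels") <- nrow(sys$channels)
  out
}

#' Median image-quality metrics versus depth
#'
#' Bins a PSF report (or several, e.g. one per array design) by depth and
#' reports the per-bin median of each metric.
#'
#' @param reports a `psf_report` or named list of them (names label designs).
#' @param depth_band analysis band (mm), default 5-25.
#' @param bin_mm depth bin width (mm).
#' @return data.frame with columns `design`, `depth_lo`, `depth_hi`, `n`, and
#'   median `fwhm_mm`, `loc_err_mm`, `eff_res_mm`, `snr`. Empty bins are
#'   omitted with a warning.
#' @export
depth_profile <- function(reports, depth_band = c(5, 25), bin_mm = 5) {
  if (inherits(reports, "psf_report")) reports <- list(design = reports)
  breaks <- seq(depth_band[1], depth_band[2], by = bin_mm)
  if (breaks[length(breaks)] < depth_band[2])
    breaks <- c(breaks, depth_band[2])
  rows <- list()
  for (nm in names(reports)) {
    r <- reports[[nm]]
    for (b in seq_len(length(breaks) - 1)) {
      lo <- breaks[b]; hi <- breaks[b + 1]
      sel <- r$depth_mm >= lo &
        (if (b == length(breaks) - 1) r$depth_mm <= hi else r$depth_mm < hi)
      if (!any(sel)) {
        warning(sprintf("empty depth bin [%g, %g) for design %s", lo, hi, nm))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        design = nm, depth_lo = lo, depth_hi = hi, n = sum(sel),
        fwhm_mm = stats::median(r$fwhm_mm[sel]),
        loc_err_mm = stats::median(r$loc_err_mm[sel]),
        eff_res_mm = stats::median(r$eff_res_mm[sel]),
        snr = stats::median(r$snr[sel]))
    }
  }
  do.call(rbind, rows)
}
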