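#' Channel time-series container
#'
#' Channels x frames numeric matrix plus frame rate and unit/wavelength tags.
#' Used for raw intensities, log-ratios, and everything in between.
#'
#' @param values channels x frames numeric matrix.
#' @param fs frame rate in Hz.
#' @param unit "intensity" or "log-ratio".
#' @param channels optional `channel_set` (or data.frame) describing the rows.
#' @param wavelength_nm optional single wavelength tag for the whole series.
#' @return object of class `dot_series`.
#' @export
dot_series <- function(values, fs, unit = c("log-ratio", "intensity"),
                       channels = NULL, wavelength_nm = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("series values must be finite")
  if (fs <= 0) stop("frame rate must be positive")
  structure(list(values = values, fs = fs, unit = unit,
                 channels = channels, wavelength_nm = wavelength_nm),
            class = "dot_series")
}

#' @export
print.dot_series <- function(x, ...) {
  cat(sprintf("<dot_series> %d channels x %d frames @ %.3g Hz [%s]%s\n",
              nrow(x$values), ncol(x$values), x$fs, x$unit,
              if (is.null(x$wavelength_nm)) "" else
                sprintf(", %g nm", x$wavelength_nm)))
  invisible(x)
}

# CW diffusion Green's function (fluence) of a semi-infinite medium with an
# extrapolated boundary: real isotropic source at depth z_src, negative image
# source mirrored about the plane z = -z_b. `pts` are field points (n x 3,
# z = depth), `src_xy` the source's surface coordinates. Distances are clamped
# below `r_min` to avoid the 1/r singularity at the source point.
greens_semi_infinite <- function(pts, src_xy, z_src, mua, musp,
                                 r_min = 1e-3, reff = 0.493) {
  D <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / D)
  zb <- 2 * D * (1 + reff) / (1 - reff)
  dx <- pts[, 1] - src_xy[1]
  dy <- pts[, 2] - src_xy[2]
  r1 <- sqrt(dx^2 + dy^2 + (pts[, 3] - z_src)^2)
  r2 <- sqrt(dx^2 + dy^2 + (pts[, 3] + z_src + 2 * zb)^2)
  r1 <- pmax(r1, r_min)
  r2 <- pmax(r2, r_min)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Analytic slab sensitivity (Jacobian) matrix
#'
#' Builds the continuous-wave Rytov sensitivity matrix A for a homogeneous
#' semi-infinite slab: A[m, v] relates a voxel absorption change (mm^-1) to
#' the channel's log-ratio change. Each entry is the adjoint product of
#' semi-infinite-medium diffusion Green's functions,
#' G(source, voxel) * G(voxel, detector) * h_v / G(source, detector), with the
#' effective isotropic source placed one transport mean free path
#' (z0 = 1/mu_s') below the optode, an extrapolated boundary with effective
#' reflection coefficient 0.493, and voxel volume h_v. Source-voxel distances
#' are clamped at half a voxel spacing; any negative product left by the
#' image-source subtraction is clamped to zero so sensitivities are
#' nonnegative.
#'
#' @param grid an `optode_grid`; all optodes must lie on the z = 0 boundary.
#' @param channels a `channel_set` built from `grid`.
#' @param phantom a [slab_phantom()] with properties for `wavelength`.
#' @param wavelength wavelength tag (must match a `phantom$optical` entry and
#'   the `channel_set` rows used).
#' @return object of class `sensitivity_matrix`: list with `A` (channels x
#'   voxels), `channels` (the rows of `channels` at this wavelength),
#'   `phantom`, `wavelength`.
#' @export
slab_sensitivity <- function(grid, channels, phantom, wavelength) {
  sys <- blocked_slab_system(grid, channels, phantom, wavelength,
                             block_voxels = prod(phantom$dims))
  A <- sys$block(seq_len(prod(phantom$dims)))
  structure(list(A = A, channels = sys$channels, phantom = phantom,
                 wavelength = wavelength),
            class = "sensitivity_matrix")
}

# Shared machinery for assembling the slab Jacobian in voxel blocks: the
# per-optode fluence matrix G (optodes x voxels) is precomputed once, and
# `block(cols)` materializes the requested Jacobian columns on demand as
# pmax(0, G[src,] * G[det,]) * h_v / G_sd. This keeps the peak footprint at a
# few channel x block matrices even for ~100k-voxel phantoms.
blocked_slab_system <- function(grid, channels, phantom, wavelength,
                                block_voxels = 8192) {
  stopifnot(inherits(grid, "optode_grid"), inherits(phantom, "slab_phantom"))
  if (any(abs(grid$z) > 1e-9))
    stop("geometry error: all optodes must lie on the z = 0 boundary plane")
  op <- phantom$optical[[as.character(wavelength)]]
  if (is.null(op))
    stop("phantom has no optical properties for wavelength ", wavelength)
  ch <- channels[channels$wavelength_nm == wavelength, , drop = FALSE]
  if (nrow(ch) == 0) stop("channel set has no rows at wavelength ", wavelength)
  z0 <- 1 / op$musp
  r_min <- phantom$voxel_mm / 2
  pts <- voxel_centers(phantom)
  h_v <- phantom$voxel_mm^3
  used <- sort(unique(c(ch$source_id, ch$detector_id)))
  G <- matrix(0, length(used), nrow(pts))
  for (i in seq_along(used)) {
    o <- grid[grid$optode_id == used[i], ]
    G[i, ] <- greens_semi_infinite(pts, c(o$x, o$y), z0,
                                   op$mua, op$musp, r_min = r_min)
  }
  idx <- match(ch$source_id, used)
  jdx <- match(ch$detector_id, used)
  # normalizing source->detector Green's function (detector on the surface)
  det_pos <- grid[match(ch$detector_id, grid$optode_id), ]
  src_pos <- grid[match(ch$source_id, grid$optode_id), ]
  gsd <- vapply(seq_len(nrow(ch)), function(m) greens_semi_infinite(
    matrix(c(det_pos$x[m], det_pos$y[m], 0), 1, 3),
    c(src_pos$x[m], src_pos$y[m]), z0, op$mua, op$musp, r_min = r_min),
    numeric(1))
  nv <- nrow(pts)
  starts <- seq(1L, nv, by = as.integer(block_voxels))
  blocks <- lapply(starts, function(s) s:min(s + block_voxels - 1L, nv))
  list(
    channels = ch,
    blocks = blocks,
    block = function(cols) {
      Ab <- G[idx, cols, drop = FALSE] * G[jdx, cols, drop = FALSE]
      Ab[Ab < 0] <- 0
      Ab * (h_v / gsd)    # row-wise scale (recycles down columns)
    })
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d channels x %d voxels @ %g nm\n",
              nrow(x$A), ncol(x$A), x$wavelength))
  invisible(x)
}

#' Distance-dependent channel noise model
#'
#' Zero-mean Gaussian measurement noise, independent across channels, whose
#' standard deviation grows exponentially with source-detector separation
#' (mirroring the log-linear light fall-off): sigma(d) = sigma_ref *
#' exp((d - d_ref)/tau). Cross-channel covariance is zero by construction.
#'
#' @param sigma_ref log-ratio noise SD at the reference separation.
#' @param d_ref reference separation (mm).
#' @param tau e-folding distance (mm).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(sigma_ref = 0.0075, d_ref = 10, tau = 15) {
  if (sigma_ref <= 0 || tau <= 0) stop("sigma_ref and tau must be positive")
  structure(list(sigma_ref = sigma_ref, d_ref = d_ref, tau = tau),
            class = "noise_model")
}

#' @rdname noise_model
#' @param noise a `noise_model`.
#' @param separation_mm channel separation(s), mm.
#' @export
noise_sigma <- function(noise, separation_mm) {
  stopifnot(inherits(noise, "noise_model"), all(separation_mm > 0))
  noise$sigma_ref * exp((separation_mm - noise$d_ref) / noise$tau)
}

#' Simulate channel measurements from a voxel absorption series
#'
#' Applies the linear forward model y(t) = A x(t) + n(t) frame by frame.
#' Noise is zero-mean Gaussian, independent per channel and frame, with SD
#' given by the noise model at each channel's separation; `noise = NULL`
#' returns the noiseless projection.
#'
#' @param A a [slab_sensitivity()] result.
#' @param x a [voxel_image()] (vector or voxels x frames matrix) on A's
#'   phantom grid.
#' @param noise a [noise_model()] or NULL.
#' @param seed integer RNG seed (required when noise is given).
#' @param fs frame rate tag for the output series (Hz).
#' @return a [dot_series()] of log-ratios.
#' @export
simulate_measurements <- function(A, x, noise = NULL, seed = NULL, fs = 7.8) {
  stopifnot(inherits(A, "sensitivity_matrix"))
  xv <- if (inherits(x, "voxel_image")) x$values else as.matrix(x)
  if (nrow(xv) != ncol(A$A))
    stop("shape error: x has ", nrow(xv), " voxels but A has ", ncol(A$A))
  y <- A$A %*% xv
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    sig <- noise_sigma(noise, A$channels$separation_mm)
    old <- .Random.seed_save()
    set.seed(seed)
    y <- y + matrix(stats::rnorm(length(y), sd = rep(sig, ncol(y))),
                    nrow(y), ncol(y))
    .Random.seed_restore(old)
  }
  dot_series(y, fs = fs, unit = "log-ratio", channels = A$channels,
             wavelength_nm = A$wavelength)
}

# save/restore the global RNG state so seeded simulators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
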