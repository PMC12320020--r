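# Synthetic two-wavelength session generator: composes the forward model,
# haemoglobin spectroscopy, an HRF-convolved block design, a shared
# superficial (scalp) signal, a ~1 Hz cardiac component, and
# distance-dependent channel noise into complete sessions with known ground
# truth. Every downstream stage of the package is testable on its output.

#' Specification of a synthetic session
#'
#' Collects everything needed to generate a session: array geometry, phantom,
#' stimulus protocol, activation ROIs, and the physiological/instrumental
#' noise structure. Defaults emulate one very-high-density pad over a
#' two-layer slab: 9.75 mm pitch, 7.8 Hz frame rate, distance-dependent
#' channel noise, a low-frequency scalp signal coupled most strongly to the
#' shortest channels, a 1 Hz cardiac component, and a focal brain activation
#' with the canonical dHbO +1 / dHbR -0.3 amplitude pattern (micromolar).
#'
#' @param pitch_mm optode pitch (default 9.75).
#' @param n_rows,n_cols lattice size (default 6 x 6).
#' @param phantom a [slab_phantom()]; default 72 x 72 x 30 mm at 3 mm voxels.
#' @param design a [stimulus_design()]; default the auditory localizer
#'   protocol (6 x 15 s blocks, 15 s rest).
#' @param rois list of ROI specs: each `list(center, radius_mm, condition,
#'   dHbO_uM, dHbR_uM)`. Centers must lie in the brain layer. `condition`
#'   names the design condition driving the ROI (NULL = first condition).
#' @param noise a [noise_model()] for channel noise, or NULL for noiseless.
#' @param superficial_amp SD of the shared scalp signal at the shortest
#'   channels (log-ratio units; 0 disables).
#' @param cardiac_amp amplitude of the cardiac sinusoid at the shortest
#'   channels (log-ratio units; 0 disables).
#' @param cardiac_hz cardiac frequency (default 1 Hz).
#' @param fs frame rate (default 7.8 Hz).
#' @param max_separation_mm channel cutoff (default 40).
#' @param intensity0 full-scale intensity of the shortest channels for the
#'   raw-intensity view.
#' @param falloff_decade_mm light fall-off: one decade of intensity per this
#'   many mm of separation (default 5, giving ~10^6 dynamic range over a
#'   9.75-40 mm channel set).
#' @return object of class `session_spec`.
#' @export
session_spec <- function(pitch_mm = 9.75, n_rows = 6, n_cols = 6,
                         phantom = slab_phantom(c(72, 72, 30), voxel_mm = 3),
                         design = localizer_design("auditory"),
                         rois = list(list(center = c(36, 36, 14),
                                          radius_mm = 8,
                                          condition = NULL,
                                          dHbO_uM = 1, dHbR_uM = -0.3)),
                         noise = noise_model(),
                         superficial_amp = 0.01,
                         cardiac_amp = 0.03, cardiac_hz = 1,
                         fs = 7.8, max_separation_mm = 40,
                         intensity0 = 1, falloff_decade_mm = 5) {
  if (fs <= 2) stop("frame rate must exceed 2 Hz")
  for (r in rois) {
    if (r$center[3] < phantom$superficial_thickness_mm)
      stop("ROI center must lie in the brain layer")
  }
  structure(as.list(environment()), class = "session_spec")
}

# spherical ROI membership on the phantom grid, restricted to the brain layer
roi_voxels <- function(phantom, center, radius_mm, brain_only = TRUE) {
  pts <- voxel_centers(phantom)
  vox <- which(sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
                      (pts[, 3] - center[3])^2) <= radius_mm)
  if (brain_only) vox <- vox[voxel_layers(phantom)[vox] == "brain"]
  vox
}

# band-limited random walk used as the shared superficial (scalp) signal
superficial_course <- function(n, fs, band = c(0.08, 0.12)) {
  x <- cumsum(stats::rnorm(n))
  v <- butter_filtfilt(matrix(x, 1), fs, band[1], "high")
  v <- butter_filtfilt(v, fs, band[2], "low")
  v <- as.vector(v)
  s <- stats::sd(v)
  if (s == 0) v else v / s
}

#' Generate a complete synthetic two-wavelength session
#'
#' Builds the sensitivity matrices for the spec's geometry, synthesizes the
#' chromophore ground truth (HRF-convolved boxcars inside each ROI), converts
#' it to per-wavelength absorption via the extinction matrix, projects it
#' through the forward model, and adds the superficial signal, the cardiac
#' component, and channel noise:
#'   y_lambda = A_lambda x_lambda + c_m s(t) + c_m a sin(2 pi f t) + n.
#' The coupling c_m decays exponentially with channel separation so the
#' superficial terms load most on nn1 channels. A raw-intensity view
#' Phi = Phi0 10^(-d/decade) exp(-y) is also produced.
#'
#' @param spec a [session_spec()].
#' @param seed integer seed; the session is a deterministic function of
#'   (spec, seed).
#' @return object of class `dot_session`: list with `grid`, `channels`,
#'   `phantom`, `A` (per wavelength), `y` (log-ratio [dot_series()] per
#'   wavelength), `raw` (intensity series per wavelength), `design`, `truth`
#'   (ROI voxels, condition responses, chromophore amplitudes, seed).
#' @export
make_session <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "session_spec"))
  ph <- spec$phantom
  ext <- ph$dims * ph$voxel_mm
  span_x <- (spec$n_cols - 1) * spec$pitch_mm
  span_y <- (spec$n_rows - 1) * spec$pitch_mm
  grid <- checkerboard_grid(spec$pitch_mm, spec$n_rows, spec$n_cols,
                            origin = c((ext[1] - span_x) / 2,
                                       (ext[2] - span_y) / 2, 0))
  channels <- enumerate_channels(grid, spec$max_separation_mm)
  wls <- sort(unique(channels$wavelength_nm))
  A <- lapply(wls, function(w) slab_sensitivity(grid, channels, ph, w))
  names(A) <- wls

  n_frames <- floor(attr(spec$design, "run_duration_s") * spec$fs)
  tt <- (seq_len(n_frames) - 1) / spec$fs
  conds <- unique(spec$design$condition)
  # unit-amplitude HRF-convolved boxcar response per condition
  X <- build_design_matrix(spec$design, tt)
  resp <- X[, conds, drop = FALSE]

  E <- hb_extinction()
  truth_rois <- list()
  dmua <- lapply(wls, function(w) matrix(0, prod(ph$dims), n_frames))
  names(dmua) <- wls
  for (r in spec$rois) {
    vox <- roi_voxels(ph, r$center, r$radius_mm)
    cond <- if (is.null(r$condition)) conds[1] else r$condition
    course <- resp[, cond]
    dC <- c(HbO = r$dHbO_uM, HbR = r$dHbR_uM) * 1e-6   # molar
    for (w in wls) {
      amp <- sum(E[as.character(w), ] * dC)            # mm^-1 at unit response
      dmua[[as.character(w)]][vox, ] <-
        dmua[[as.character(w)]][vox, ] + amp * rep(course, each = length(vox))
    }
    truth_rois[[length(truth_rois) + 1]] <-
      list(center = r$center, radius_mm = r$radius_mm, voxels = vox,
           condition = cond, dHbO_uM = r$dHbO_uM, dHbR_uM = r$dHbR_uM)
  }

  old <- .Random.seed_save()
  set.seed(seed)
  sep <- channels$separation_mm[channels$wavelength_nm == wls[1]]
  coupling <- exp(-(sep - min(sep)) / 20)
  sup <- if (spec$superficial_amp > 0)
    spec$superficial_amp * superficial_course(n_frames, spec$fs) else NULL
  card <- if (spec$cardiac_amp > 0)
    spec$cardiac_amp * sin(2 * pi * spec$cardiac_hz * tt +
                             stats::runif(1, 0, 2 * pi)) else NULL
  y <- list(); raw <- list()
  for (w in wls) {
    wc <- as.character(w)
    yv <- A[[wc]]$A %*% dmua[[wc]]
    if (!is.null(sup)) yv <- yv + outer(coupling, sup)
    if (!is.null(card)) yv <- yv + outer(coupling, card)
    if (!is.null(spec$noise)) {
      sig <- noise_sigma(spec$noise, sep)
      yv <- yv + matrix(stats::rnorm(length(yv), sd = rep(sig, ncol(yv))),
                        nrow(yv), ncol(yv))
    }
    chw <- channels[channels$wavelength_nm == w, , drop = FALSE]
    y[[wc]] <- dot_series(yv, fs = spec$fs, unit = "log-ratio",
                          channels = chw, wavelength_nm = w)
    phi0 <- spec$intensity0 * 10^(-sep / spec$falloff_decade_mm)
    raw[[wc]] <- dot_series(phi0 * exp(-yv), fs = spec$fs,
                            unit = "intensity", channels = chw,
                            wavelength_nm = w)
  }
  .Random.seed_restore(old)
  structure(list(grid = grid, channels = channels, phantom = ph, A = A,
                 y = y, raw = raw, design = spec$design,
                 truth = list(rois = truth_rois, response = resp,
                              conditions = conds, seed = seed,
                              superficial = sup, cardiac_hz = spec$cardiac_hz,
                              coupling = coupling),
                 fs = spec$fs, spec = spec),
            class = "dot_session")
}

#' @export
print.dot_session <- function(x, ...) {
  cat(sprintf("<dot_session> %d channels x %d frames @ %g Hz, %d ROI(s), seed %d\n",
              nrow(x$channels), ncol(x$y[[1]]$values), x$fs,
              length(x$truth$rois), x$truth$seed))
  invisible(x)
}

#' Generate a movie-style session pair with a shared stimulus-driven signal
#'
#' Two runs of equal length share an identical stimulus-driven spatiotemporal
#' component: ground-truth feature traces (a smooth luminance-like trace and
#' a binary speech-like trace) are HRF-convolved, band-passed, mixed into
#' ROI-confined chromophore changes, projected through the forward model, and
#' added to independent noise realizations in each run. The signal-to-noise
#' ratio `shared_snr` is the ratio, averaged over the driven channels, of
#' the shared component's temporal SD to the channel noise SD; the driven
#' amplitude is rescaled to hit it exactly (Inf gives noise-free runs).
#'
#' @param spec a [session_spec()]; its design is ignored in favour of a
#'   continuous run of `duration_s`.
#' @param shared_snr channel-level SNR of the shared component.
#' @param duration_s run length in seconds (default 600, a 10-minute movie).
#' @param seed integer seed.
#' @return list with `run1`, `run2` (per-wavelength log-ratio
#'   [dot_series()]s), `truth` (feature regressors, ROI voxels, seed), plus
#'   `grid`, `channels`, `phantom`, `A`.
#' @export
make_movie_session <- function(spec, shared_snr = 1, duration_s = 600,
                               seed = 1) {
  stopifnot(inherits(spec, "session_spec"))
  ph <- spec$phantom
  ext <- ph$dims * ph$voxel_mm
  span_x <- (spec$n_cols - 1) * spec$pitch_mm
  span_y <- (spec$n_rows - 1) * spec$pitch_mm
  grid <- checkerboard_grid(spec$pitch_mm, spec$n_rows, spec$n_cols,
                            origin = c((ext[1] - span_x) / 2,
                                       (ext[2] - span_y) / 2, 0))
  channels <- enumerate_channels(grid, spec$max_separation_mm)
  wls <- sort(unique(channels$wavelength_nm))
  A <- lapply(wls, function(w) slab_sensitivity(grid, channels, ph, w))
  names(A) <- wls
  n_frames <- floor(duration_s * spec$fs)
  tt <- (seq_len(n_frames) - 1) / spec$fs

  old <- .Random.seed_save()
  set.seed(seed)
  # ground-truth features at 1 Hz: smooth luminance-like + binary speech-like
  n1 <- ceiling(duration_s)
  lum_raw <- as.vector(butter_filtfilt(matrix(stats::rnorm(n1), 1), 1,
                                       0.1, "low"))
  lat <- as.vector(stats::filter(stats::rnorm(n1), rep(1, 10), sides = 1))
  lat[is.na(lat)] <- 0
  speech_raw <- as.numeric(lat > 0)
  lum <- regressor_pipeline(feature_regressor("luminance", lum_raw, 1))
  speech <- regressor_pipeline(feature_regressor("speech", speech_raw, 1))
  # ROI-confined chromophore course at the session frame rate
  courses <- lapply(list(lum, speech), function(rg)
    stats::approx((seq_len(n1) - 1), rg$values, xout = tt, rule = 2)$y)
  E <- hb_extinction()
  rois <- spec$rois
  if (length(rois) < length(courses))
    rois <- rep(rois, length.out = length(courses))
  shared <- lapply(wls, function(w) matrix(0, nrow(A[[1]]$A), n_frames))
  names(shared) <- wls
  truth_rois <- list()
  for (k in seq_along(courses)) {
    r <- rois[[k]]
    vox <- roi_voxels(ph, r$center, r$radius_mm)
    dC <- c(HbO = r$dHbO_uM, HbR = r$dHbR_uM) * 1e-6
    for (w in wls) {
      wc <- as.character(w)
      amp <- sum(E[wc, ] * dC)
      xw <- matrix(0, prod(ph$dims), n_frames)
      xw[vox, ] <- amp * rep(courses[[k]], each = length(vox))
      shared[[wc]] <- shared[[wc]] + A[[wc]]$A %*% xw
    }
    truth_rois[[k]] <- list(center = r$center, radius_mm = r$radius_mm,
                            voxels = vox)
  }
  sep <- channels$separation_mm[channels$wavelength_nm == wls[1]]
  sig <- if (is.null(spec$noise)) rep(0, length(sep))
         else noise_sigma(spec$noise, sep)
  # rescale the shared component to the requested channel-level SNR over the
  # most strongly driven channels, at the most strongly driven wavelength
  cur <- max(vapply(wls, function(w) {
    ss <- apply(shared[[as.character(w)]], 1, stats::sd)
    driven <- which(ss >= stats::quantile(ss, 0.9))
    mean(ss[driven] / pmax(sig[driven], 1e-300))
  }, numeric(1)))
  scale <- if (!is.finite(shared_snr)) 1 else if (shared_snr == 0) 0 else {
    if (cur == 0) 0 else shared_snr / cur
  }
  runs <- lapply(1:2, function(i) {
    out <- list()
    for (w in wls) {
      wc <- as.character(w)
      yv <- shared[[wc]] * scale
      if (!is.null(spec$noise) && is.finite(shared_snr)) {
        yv <- yv + matrix(stats::rnorm(length(yv), sd = rep(sig, ncol(yv))),
                          nrow(yv), ncol(yv))
      }
      chw <- channels[channels$wavelength_nm == w, , drop = FALSE]
      out[[wc]] <- dot_series(yv, fs = spec$fs, unit = "log-ratio",
                              channels = chw, wavelength_nm = w)
    }
    out
  })
  .Random.seed_restore(old)
  list(run1 = runs[[1]], run2 = runs[[2]],
       truth = list(features = list(luminance = lum, speech = speech),
                    rois = truth_rois, seed = seed, scale = scale),
       grid = grid, channels = channels, phantom = ph, A = A)
}

#' Six-task localizer session suite
#'
#' One run per task label (auditory, language, visual left/right, motor
#' left/right), each with its own activation ROI at a distinct cortical
#' location, suitable for six-way template-matching decoding.
#'
#' @param seed integer seed (each run uses `seed + run index`).
#' @param noise,superficial_amp,cardiac_amp passed to [session_spec()];
#'   set `noise = NULL, superficial_amp = 0, cardiac_amp = 0` for noiseless
#'   sessions.
#' @param n_blocks blocks per run (default 6).
#' @param block_s,rest_s block and rest durations (default 15/15).
#' @param dHbO_uM,dHbR_uM ROI amplitudes.
#' @return named list of [make_session()] results, one per task.
#' @export
localizer_session_suite <- function(seed = 1, noise = noise_model(),
                                    superficial_amp = 0.01,
                                    cardiac_amp = 0.03, n_blocks = 6,
                                    block_s = 15, rest_s = 15,
                                    dHbO_uM = 1, dHbR_uM = -0.3) {
  tasks <- c("auditory", "language", "visual_left", "visual_right",
             "motor_left", "motor_right")
  centers <- list(c(18, 36, 14), c(54, 36, 14), c(45, 18, 14),
                  c(27, 18, 14), c(45, 54, 14), c(27, 54, 14))
  out <- list()
  for (i in seq_along(tasks)) {
    onsets <- rest_s + (seq_len(n_blocks) - 1) * (block_s + rest_s)
    des <- stimulus_design(onsets, rep(block_s, n_blocks),
                           rep(tasks[i], n_blocks),
                           run_duration_s = rest_s + n_blocks * (block_s + rest_s))
    sp <- session_spec(design = des,
                       rois = list(list(center = centers[[i]], radius_mm = 8,
                                        condition = tasks[i],
                                        dHbO_uM = dHbO_uM,
                                        dHbR_uM = dHbR_uM)),
                       noise = noise, superficial_amp = superficial_amp,
                       cardiac_amp = cardiac_amp)
    out[[tasks[i]]] <- make_session(sp, seed = seed + i)
  }
  out
}
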