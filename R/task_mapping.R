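# GLM response mapping: HRF-convolved block designs, per-voxel OLS betas,
# contrasts, fixed-effects group t-maps, Dice overlap, ROI block averages.

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities parameterized by their mode: a positive
#' lobe peaking at `peak` seconds and an undershoot peaking at `undershoot`
#' seconds with relative amplitude `ratio`. Normalized to unit peak. The HRF
#' is an argument everywhere it is used, so a tabulated empirical response
#' can be substituted.
#'
#' @param t time in seconds (vector).
#' @param peak mode of the positive lobe, s (default 6).
#' @param undershoot mode of the undershoot lobe, s (default 16).
#' @param ratio undershoot amplitude relative to the peak lobe (default 1/6).
#' @return numeric vector of HRF values.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

#' Stimulus event table
#'
#' @param onset,duration numeric vectors, seconds.
#' @param condition character vector of condition labels.
#' @param run_duration_s total run length in seconds.
#' @return object of class `stimulus_design` (a data.frame with attribute
#'   `run_duration_s`).
#' @export
stimulus_design <- function(onset, duration, condition, run_duration_s) {
  if (any(onset < 0) || any(onset + duration > run_duration_s))
    stop("events must lie within the run")
  d <- data.frame(onset = onset, duration = duration,
                  condition = as.character(condition))
  d <- d[order(d$onset), ]
  for (cc in unique(d$condition)) {
    e <- d[d$condition == cc, ]
    if (nrow(e) > 1 && any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)]))
      stop("events overlap within condition ", cc)
  }
  structure(d, run_duration_s = run_duration_s,
            class = c("stimulus_design", "data.frame"))
}

#' Block protocols for the standard functional localizers
#'
#' Ready-made event tables: "auditory" and "language" are 6 blocks of 15 s on
#' / 15 s off; "visual" and "motor" are 10 s stimulation / 24 s rest, 16
#' blocks alternating two lateralized conditions (left/right).
#'
#' @param task one of "auditory", "language", "visual", "motor".
#' @param lead_in_s rest before the first block (default 15).
#' @return a [stimulus_design()].
#' @export
localizer_design <- function(task = c("auditory", "language", "visual",
                                      "motor"),
                             lead_in_s = 15) {
  task <- match.arg(task)
  if (task %in% c("auditory", "language")) {
    onsets <- lead_in_s + (0:5) * 30
    stimulus_design(onsets, rep(15, 6), rep(task, 6),
                    run_duration_s = lead_in_s + 6 * 30)
  } else {
    onsets <- lead_in_s + (0:15) * 34
    cond <- paste0(task, "_", rep(c("left", "right"), 8))
    stimulus_design(onsets, rep(10, 16), cond,
                    run_duration_s = lead_in_s + 16 * 34)
  }
}

#' Build a GLM design matrix
#'
#' One boxcar regressor per condition convolved with the HRF (sampled at the
#' frame times), plus a constant and a linear drift column.
#'
#' @param design a [stimulus_design()].
#' @param frame_times frame acquisition times in seconds.
#' @param hrf function(t) returning HRF values; default [canonical_hrf()].
#' @param hrf_span_s length of the sampled HRF kernel, s.
#' @return numeric matrix frames x (conditions + 2) with column names; zero
#'   (event-less) condition columns raise a warning.
#' @export
build_design_matrix <- function(design, frame_times, hrf = canonical_hrf,
                                hrf_span_s = 32) {
  stopifnot(inherits(design, "stimulus_design"))
  if (nrow(design) == 0) stop("degenerate design: no events")
  dur <- attr(design, "run_duration_s")
  if (any(frame_times < 0) || any(frame_times > dur))
    stop("frame times must lie within the run")
  dt <- stats::median(diff(frame_times))
  # oversampled boxcar convolution, then sampled at the frame times
  os <- 0.1
  tt <- seq(0, dur, by = os)
  kern <- hrf(seq(0, hrf_span_s, by = os))
  conds <- unique(design$condition)
  X <- matrix(0, length(frame_times), length(conds) + 2,
              dimnames = list(NULL, c(conds, "constant", "drift")))
  for (ci in seq_along(conds)) {
    e <- design[design$condition == conds[ci], ]
    box <- numeric(length(tt))
    for (k in seq_len(nrow(e)))
      box[tt >= e$onset[k] & tt < e$onset[k] + e$duration[k]] <- 1
    reg <- stats::convolve(box, rev(kern), type = "open")[seq_along(tt)] * os
    X[, ci] <- stats::approx(tt, reg, xout = frame_times, rule = 2)$y
    if (max(abs(X[, ci])) < 1e-10)
      warning("condition ", conds[ci], " has a zero regressor column")
  }
  X[, "constant"] <- 1
  X[, "drift"] <- seq_along(frame_times) - mean(seq_along(frame_times))
  X
}

#' Per-voxel ordinary least squares GLM fit
#'
#' Fits every voxel's time series against the design matrix and returns
#' condition betas with standard errors from the residual variance and
#' (X'X)^-1.
#'
#' @param Y voxels x frames matrix (or [voxel_image()] series).
#' @param X design matrix from [build_design_matrix()].
#' @param se_floor lower bound applied to standard errors so that noiseless
#'   synthetic fits do not divide by zero downstream.
#' @return object of class `stat_map`: list with `beta` (voxels x regressors),
#'   `se`, `df`, `regressors`.
#' @export
fit_glm <- function(Y, X, se_floor = 1e-12) {
  yv <- if (inherits(Y, "voxel_image")) Y$values else as.matrix(Y)
  if (ncol(yv) != nrow(X)) stop("frames of Y and rows of X must match")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design-collinearity error: X is rank deficient")
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- t(qr.coef(qrX, t(yv)))                     # voxels x regressors
  fitted <- beta %*% t(X)
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums((yv - fitted)^2) / df
  se <- sqrt(outer(sigma2, diag(XtXinv)))
  se <- pmax(se, se_floor)
  dimnames(se) <- dimnames(beta)
  structure(list(beta = beta, se = se, df = df, regressors = colnames(X)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  what <- if (!is.null(x$t)) "t" else "beta"
  cat(sprintf("<stat_map> %d voxels, %s values%s\n",
              nrow(if (!is.null(x$t)) as.matrix(x$t) else x$beta), what,
              if (!is.null(x$regressors))
                paste0(" [", paste(x$regressors, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# extract a single-column beta/se pair from a stat_map
stat_column <- function(map, condition = NULL) {
  b <- map$beta; s <- map$se
  if (is.null(condition)) condition <- 1
  list(beta = b[, condition], se = s[, condition])
}

#' Contrast between two condition maps
#'
#' Beta difference with propagated standard error sqrt(se_a^2 + se_b^2).
#' The two maps may be the same [fit_glm()] object with different condition
#' columns (e.g. left vs right lateralized stimuli).
#'
#' @param map_a,map_b `stat_map`s (from [fit_glm()]).
#' @param cond_a,cond_b condition names or column indices.
#' @return a `stat_map` with single-column `beta` and `se`.
#' @export
contrast <- function(map_a, map_b, cond_a = 1, cond_b = 1) {
  a <- stat_column(map_a, cond_a)
  b <- stat_column(map_b, cond_b)
  if (length(a$beta) != length(b$beta)) stop("shape error: grids differ")
  structure(list(beta = cbind(contrast = a$beta - b$beta),
                 se = cbind(contrast = sqrt(a$se^2 + b$se^2)),
                 df = min(map_a$df, map_b$df), regressors = "contrast"),
            class = "stat_map")
}

#' Group fixed-effects t-statistic map
#'
#' Combines per-subject betas and standard errors into a group t-map:
#' t_v = sum_s beta_sv / sqrt(sum_s se_sv^2) (default), or the
#' inverse-variance-weighted variant
#' t_v = (sum_s beta_sv / se_sv^2) / sqrt(sum_s 1 / se_sv^2).
#'
#' @param maps list of `stat_map`s on a shared grid.
#' @param condition condition name or column index to combine.
#' @param weighted use the inverse-variance weighting (default FALSE).
#' @return a `stat_map` with a `t` vector.
#' @export
group_fixed_effects_t <- function(maps, condition = 1, weighted = FALSE) {
  stopifnot(length(maps) >= 1)
  B <- sapply(maps, function(m) stat_column(m, condition)$beta)
  S <- sapply(maps, function(m) stat_column(m, condition)$se)
  B <- as.matrix(B); S <- as.matrix(S)
  t_v <- if (weighted) {
    rowSums(B / S^2) / sqrt(rowSums(1 / S^2))
  } else {
    rowSums(B) / sqrt(rowSums(S^2))
  }
  structure(list(t = t_v, beta = as.matrix(rowMeans(B)),
                 se = as.matrix(sqrt(rowSums(S^2)) / ncol(S)),
                 df = sum(vapply(maps, function(m) m$df, 1)),
                 n_subjects = length(maps)),
            class = "stat_map")
}

# values used for thresholding: t if present, else first beta column
map_values <- function(m) {
  if (inherits(m, "stat_map")) {
    if (!is.null(m$t)) as.vector(m$t) else m$beta[, 1]
  } else if (inherits(m, "voxel_image")) m$values[, 1]
  else as.vector(m)
}

#' Dice overlap of two thresholded maps
#'
#' Each map is binarized at `frac` times its own maximum; Dice =
#' 2|X n Y| / (|X| + |Y|).
#'
#' @param map1,map2 `stat_map`s, `voxel_image`s or numeric vectors on a
#'   shared grid.
#' @param frac threshold fraction in (0, 1), conventionally 0.25 or 0.5.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(map1, map2, frac = 0.5) {
  if (frac <= 0 || frac >= 1) stop("frac must be in (0,1)")
  v1 <- map_values(map1); v2 <- map_values(map2)
  if (length(v1) != length(v2)) stop("shape error: grids differ")
  if (max(v1) <= 0 || max(v2) <= 0)
    stop("degenerate map: non-positive maximum")
  b1 <- v1 >= frac * max(v1)
  b2 <- v2 >= frac * max(v2)
  2 * sum(b1 & b2) / (sum(b1) + sum(b2))
}

#' ROI block-averaged haemoglobin time traces
#'
#' Defines a region of interest by thresholding a (group) t-map at `frac` of
#' its maximum, extracts the ROI-mean trace of each chromophore series,
#' epochs it around every block onset, and returns the across-block mean and
#' standard error.
#'
#' @param hemo named list of voxels x frames matrices or `voxel_image`s
#'   (e.g. HbO/HbR/HbT from [spectroscopy()]).
#' @param t_map map used to define the ROI.
#' @param design a [stimulus_design()]; all events are used.
#' @param fs frame rate of `hemo` in Hz.
#' @param frac ROI threshold fraction (default 0.5).
#' @param window_s epoch length from block onset, s; defaults to the maximum
#'   block duration plus 15 s of recovery.
#' @return data.frame with `time_s`, and per chromophore `mean` and `se`
#'   columns; attribute `n_blocks`.
#' @export
roi_block_average <- function(hemo, t_map, design, fs = 1, frac = 0.5,
                              window_s = NULL) {
  v <- map_values(t_map)
  if (max(v) <= 0) stop("degenerate map: non-positive maximum")
  roi <- which(v >= frac * max(v))
  if (length(roi) == 0) stop("empty ROI")
  if (nrow(design) < 2) stop("at least 2 blocks are required")
  if (is.null(window_s)) window_s <- max(design$duration) + 15
  n_ep <- floor(window_s * fs)
  time_s <- (seq_len(n_ep) - 1) / fs
  out <- data.frame(time_s = time_s)
  for (nm in names(hemo)) {
    m <- hemo[[nm]]
    m <- if (inherits(m, "voxel_image")) m$values else as.matrix(m)
    trace <- colMeans(m[roi, , drop = FALSE])
    ep <- sapply(design$onset, function(on) {
      i0 <- floor(on * fs) + 1
      idx <- i0:(i0 + n_ep - 1)
      if (max(idx) > length(trace)) rep(NA_real_, n_ep) else trace[idx]
    })
    ok <- colSums(is.na(ep)) == 0
    ep <- ep[, ok, drop = FALSE]
    out[[paste0(nm, "_mean")]] <- rowMeans(ep)
    out[[paste0(nm, "_se")]] <- apply(ep, 1, stats::sd) / sqrt(ncol(ep))
  }
  attr(out, "n_blocks") <- sum(!is.na(design$onset))
  out
}
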