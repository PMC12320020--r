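#' Regularized inverse operator for DOT image reconstruction
#'
#' Builds the Tikhonov + spatially-variant regularized pseudoinverse used to
#' invert the sensitivity matrix. The spatially-variant term counteracts the
#' surface bias of depth-dependent sensitivity: each voxel's column is scaled
#' by 1/L_v with
#'   L_v = sqrt( diag(A'A)_v + lambda2 * max_v diag(A'A)_v ),
#' giving the column-normalized matrix A~ = A diag(1/L). The Tikhonov step is
#' solved in measurement (dual) space,
#'   x = diag(1/L) A~' (A~ A~' + lambda1 * s * I)^-1 y,
#' where by default s is the largest eigenvalue of A~ A~' (options: the
#' largest diagonal entry, or 1 for an unscaled penalty).
#'
#' The operator is factored once (Cholesky of the regularized Gram matrix);
#' [reconstruct()] then costs one triangular solve plus one matrix product
#' per frame.
#'
#' @param A a [slab_sensitivity()] result, or a plain channels x voxels
#'   matrix.
#' @param lambda1 Tikhonov regularization weight (default 0.01).
#' @param lambda2 spatially-variant regularization weight (default 0.1).
#' @param smax_scale how to scale lambda1: "eigen" (largest eigenvalue of
#'   A~A~', the default), "diag" (largest diagonal entry), or "none".
#' @return object of class `inverse_operator`.
#' @export
inverse_operator <- function(A, lambda1 = 0.01, lambda2 = 0.1,
                             smax_scale = c("eigen", "diag", "none")) {
  smax_scale <- match.arg(smax_scale)
  meta <- NULL
  if (inherits(A, "sensitivity_matrix")) { meta <- A; A <- A$A }
  A <- as.matrix(A)
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be nonnegative")
  cs <- colSums(A^2)                       # diag(A'A)
  if (max(cs) == 0) stop("singular operator: sensitivity matrix is all zero")
  L <- sqrt(cs + lambda2 * max(cs))
  Linv <- 1 / L
  At <- A * rep(Linv, each = nrow(A))      # A~ = A diag(1/L)
  M0 <- tcrossprod(At)                     # A~ A~'
  s <- switch(smax_scale,
              eigen = largest_eigenvalue(M0),
              diag  = max(diag(M0)),
              none  = 1)
  M <- M0 + diag(lambda1 * s, nrow(M0))
  R <- tryCatch(chol(M), error = function(e)
    stop("singular operator: regularized Gram matrix is not positive definite"))
  structure(list(Atilde = At, Linv = Linv, cholM = R,
                 lambda1 = lambda1, lambda2 = lambda2, s = s,
                 meta = meta),
            class = "inverse_operator")
}

# largest eigenvalue of a symmetric PSD matrix: exact for small systems,
# power iteration (deterministic start, tol 1e-10) for large ones
largest_eigenvalue <- function(M, tol = 1e-10, max_iter = 5000) {
  n <- nrow(M)
  if (n <= 512)
    return(max(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
  v <- rowSums(M)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  v <- v / nv
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    lam_new <- sqrt(sum(w^2))
    if (lam_new == 0) return(0)
    v <- as.vector(w) / lam_new
    if (abs(lam_new - lam) <= tol * lam_new) break
    lam <- lam_new
  }
  lam_new
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d channels -> %d voxels, lambda1=%g, lambda2=%g\n",
              nrow(x$Atilde), ncol(x$Atilde), x$lambda1, x$lambda2))
  invisible(x)
}

#' Reconstruct voxel absorption images from channel measurements
#'
#' Frame-wise application of an [inverse_operator()] to a channels x frames
#' measurement matrix (or `dot_series`), returning voxels x frames absorption
#' changes.
#'
#' @param op an [inverse_operator()].
#' @param y a `dot_series` or channels x frames matrix, channel order matching
#'   the sensitivity matrix the operator was built from.
#' @return a [voxel_image()] when phantom metadata is available, otherwise a
#'   voxels x frames matrix.
#' @export
reconstruct <- function(op, y) {
  stopifnot(inherits(op, "inverse_operator"))
  yv <- if (inherits(y, "dot_series")) y$values else as.matrix(y)
  if (nrow(yv) != nrow(op$Atilde))
    stop("shape error: y has ", nrow(yv), " channels but the operator expects ",
         nrow(op$Atilde))
  z <- backsolve(op$cholM, forwardsolve(t(op$cholM), yv))
  x <- crossprod(op$Atilde, z) * op$Linv
  if (!is.null(op$meta))
    voxel_image(x, op$meta$phantom, unit = "dmua_mm-1")
  else x
}

#' Haemoglobin extinction-coefficient matrix
#'
#' Packaged 2x2 extinction matrix E for the 685/830 nm laser lines (rows =
#' wavelengths, columns = HbO, HbR), from the standard compiled haemoglobin
#' molar extinction spectra, converted to natural-log base and mm^-1 M^-1
#' (log-ratio measurements use the natural logarithm). Override with your own
#' matrix to use different lines or units.
#'
#' @return 2x2 numeric matrix with dimnames.
#' @export
hb_extinction <- function() {
  # base-10 molar extinction (cm^-1/M): 685 nm HbO2 294.5 / Hb 2188.9;
  # 830 nm HbO2 974.0 / Hb 693.0; x ln(10)/10 -> natural log, mm^-1/M
  e10 <- matrix(c(294.5, 2188.9,
                  974.0, 693.0), nrow = 2, byrow = TRUE)
  E <- e10 * log(10) / 10
  dimnames(E) <- list(c("685", "830"), c("HbO", "HbR"))
  E
}

#' Two-wavelength spectroscopy: absorption to haemoglobin changes
#'
#' Per-voxel inversion of the extinction matrix, dC = E^-1 x, converting
#' paired absorption-change images at the two wavelengths into oxy- and
#' deoxy-haemoglobin concentration changes; total haemoglobin is their sum.
#'
#' @param x685,x830 [voxel_image()]s (or matrices) of absorption change at
#'   each wavelength, same grid and frame count.
#' @param E 2x2 extinction matrix, rows in the order (685, 830), columns
#'   (HbO, HbR); default [hb_extinction()].
#' @return list of `voxel_image`s (or matrices) `HbO`, `HbR`, `HbT`.
#' @export
spectroscopy <- function(x685, x830, E = hb_extinction()) {
  ph <- NULL
  v685 <- x685; v830 <- x830
  if (inherits(x685, "voxel_image")) { ph <- x685$phantom; v685 <- x685$values }
  if (inherits(x830, "voxel_image")) {
    if (!is.null(ph) && !identical(ph$dims, x830$phantom$dims))
      stop("images must share a voxel grid")
    ph <- if (is.null(ph)) x830$phantom else ph
    v830 <- x830$values
  }
  v685 <- as.matrix(v685); v830 <- as.matrix(v830)
  if (!all(dim(v685) == dim(v830)))
    stop("images must share a voxel grid and frame count")
  if (abs(det(E)) < .Machine$double.eps * max(abs(E))^2 * 4)
    stop("spectral singularity: extinction matrix is not invertible")
  Einv <- solve(E)
  hbo <- Einv[1, 1] * v685 + Einv[1, 2] * v830
  hbr <- Einv[2, 1] * v685 + Einv[2, 2] * v830
  wrap <- function(v, unit) {
    if (is.null(ph)) v else voxel_image(v, ph, unit = unit)
  }
  list(HbO = wrap(hbo, "dHbO"), HbR = wrap(hbr, "dHbR"),
       HbT = wrap(hbo + hbr, "dHbT"))
}
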