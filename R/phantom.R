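#' Two-layer slab head phantom
#'
#' A rectangular slab on a regular voxel grid standing in for the head:
#' the boundary plane is z = 0 with depth increasing along +z, a superficial
#' (scalp/skull) layer down to `superficial_thickness_mm`, and "brain" below.
#' Per-wavelength baseline absorption (mu_a) and reduced scattering (mu_s')
#' are stored for the continuous-wave diffusion forward model.
#'
#' Default optical properties are typical adult-head values at the two laser
#' lines: 685 nm mu_a 0.019 / mu_s' 1.31 mm^-1 and 830 nm mu_a 0.021 /
#' mu_s' 1.07 mm^-1.
#'
#' @param extent_mm length-3 numeric, slab extent in x/y/z (mm); z is depth.
#' @param voxel_mm isotropic voxel spacing (mm).
#' @param superficial_thickness_mm depth of the superficial layer (mm).
#' @param optical named list per wavelength tag, each a list(mua, musp) in
#'   mm^-1.
#' @param origin x/y position of the first voxel centre (mm); voxel centres
#'   start half a spacing below the surface in z.
#' @return object of class `slab_phantom`.
#' @export
slab_phantom <- function(extent_mm = c(160, 160, 30), voxel_mm = 2,
                         superficial_thickness_mm = 10,
                         optical = list(
                           `685` = list(mua = 0.019, musp = 1.31),
                           `830` = list(mua = 0.021, musp = 1.07)),
                         origin = c(0, 0)) {
  if (voxel_mm <= 0) stop("voxel_mm must be positive")
  for (w in names(optical)) {
    op <- optical[[w]]
    if (op$mua <= 0) stop("mua must be positive")
    if (op$musp <= 10 * op$mua)
      stop("musp must exceed 10*mua for the diffusion approximation")
  }
  dims <- pmax(1L, as.integer(round(extent_mm / voxel_mm)))
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_mm
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_mm
  zs <- (seq_len(dims[3]) - 0.5) * voxel_mm   # depth of voxel centres
  ph <- list(dims = dims, voxel_mm = voxel_mm,
             xs = xs, ys = ys, zs = zs,
             superficial_thickness_mm = superficial_thickness_mm,
             optical = optical)
  class(ph) <- "slab_phantom"
  ph
}

#' @export
print.slab_phantom <- function(x, ...) {
  cat(sprintf("<slab_phantom> %dx%dx%d voxels @ %.3g mm (%.0fx%.0fx%.0f mm), superficial layer %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_mm,
              x$dims[1] * x$voxel_mm, x$dims[2] * x$voxel_mm,
              x$dims[3] * x$voxel_mm, x$superficial_thickness_mm))
  invisible(x)
}

#' Voxel-centre coordinates of a phantom
#'
#' @param phantom a [slab_phantom()].
#' @return n_voxels x 3 matrix of (x, y, z) centres in mm; voxel order is
#'   x fastest, then y, then z (column-major over the grid), matching
#'   the column order of sensitivity matrices built on the phantom.
#' @export
voxel_centers <- function(phantom) {
  g <- expand.grid(x = phantom$xs, y = phantom$ys, z = phantom$zs)
  as.matrix(g)
}

#' Per-voxel layer labels
#'
#' @param phantom a [slab_phantom()].
#' @return character vector, "superficial" where the voxel centre is shallower
#'   than the superficial thickness, else "brain".
#' @export
voxel_layers <- function(phantom) {
  z <- voxel_centers(phantom)[, 3]
  ifelse(z < phantom$superficial_thickness_mm, "superficial", "brain")
}

#' Voxel image on a phantom grid
#'
#' Thin container pairing a values vector (or voxels x time matrix) with its
#' phantom and a unit tag.
#'
#' @param values numeric vector of length n_voxels, or matrix with n_voxels
#'   rows (columns = time or realizations).
#' @param phantom the [slab_phantom()] the values live on.
#' @param unit free-form unit tag, e.g. "dmua_mm-1", "dHbO".
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(values, phantom, unit = "dmua_mm-1") {
  nv <- prod(phantom$dims)
  if (is.matrix(values)) {
    if (nrow(values) != nv) stop("values rows must match phantom voxel count")
  } else {
    if (length(values) != nv) stop("values length must match phantom voxel count")
    values <- matrix(values, ncol = 1)
  }
  if (!all(is.finite(values))) stop("voxel values must be finite")
  structure(list(values = values, phantom = phantom, unit = unit),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %d voxels x %d frames [%s], range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Flat voxel index from integer grid coordinates
#'
#' @param phantom a [slab_phantom()].
#' @param i,j,k 1-based grid indices along x, y, z (k indexes depth).
#' @return integer flat index into the phantom's voxel order.
#' @export
voxel_index <- function(phantom, i, j, k) {
  d <- phantom$dims
  stopifnot(all(i >= 1 & i <= d[1]), all(j >= 1 & j <= d[2]),
            all(k >= 1 & k <= d[3]))
  (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
}
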