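#' Build a checkerboard source/detector lattice
#'
#' Constructs a planar square lattice of optodes in which sources and
#' detectors alternate in a checkerboard pattern, the layout used by
#' high-density DOT imaging pads. Rows run along y, columns along x, and all
#' optodes lie in the z = 0 surface plane (depth increases with +z into the
#' slab). An optode at (row, col) is a source when (row + col) is even and a
#' detector when odd (0-based parity).
#'
#' @param pitch_mm lattice constant: nearest-neighbour optode spacing in mm
#'   (e.g. 9.75 for a very-high-density pad, 13 for a conventional
#'   high-density pad).
#' @param n_rows,n_cols lattice dimensions; both must be at least 2.
#' @param origin length-3 numeric, position of the (row 0, col 0) optode in mm.
#' @param panel label attached to every optode (used when several pads are
#'   combined).
#' @return an object of class `optode_grid`: a data.frame with columns
#'   `optode_id`, `x`, `y`, `z`, `role` ("source"/"detector"), `panel`, and
#'   attribute `pitch_mm`.
#' @examples
#' g <- checkerboard_grid(9.75, 4, 4)
#' table(g$role)
#' @export
checkerboard_grid <- function(pitch_mm, n_rows, n_cols,
                              origin = c(0, 0, 0), panel = "P1") {
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1 || pitch_mm <= 0)
    stop("pitch_mm must be a positive number")
  if (n_rows < 2 || n_cols < 2)
    stop("grid must be at least 2x2")
  rc <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  role <- ifelse((rc$row + rc$col) %% 2 == 0, "source", "detector")
  g <- data.frame(
    optode_id = seq_len(nrow(rc)),
    x = origin[1] + rc$col * pitch_mm,
    y = origin[2] + rc$row * pitch_mm,
    z = origin[3],
    role = role,
    panel = panel,
    stringsAsFactors = FALSE
  )
  class(g) <- c("optode_grid", "data.frame")
  attr(g, "pitch_mm") <- pitch_mm
  g
}

#' @export
print.optode_grid <- function(x, ...) {
  cat(sprintf("<optode_grid> %d optodes (%d sources, %d detectors), pitch %.4g mm\n",
              nrow(x), sum(x$role == "source"), sum(x$role == "detector"),
              attr(x, "pitch_mm")))
  invisible(x)
}

#' Distance classes of an infinite checkerboard lattice
#'
#' First `k` distinct source-detector separation classes of an alternating
#' checkerboard lattice with the given pitch, in ascending order. On such a
#' lattice a source's opposite-role neighbours sit at integer offsets
#' (i, j) with i + j odd, so the classes are pitch times the sorted distinct
#' values of sqrt(i^2 + j^2): 1, sqrt(5), 3, sqrt(13), sqrt(17), ...
#' For a 9.75 mm pitch the fifth class is ~40 mm, which is why DOT systems
#' built on this lattice cap channels at 40 mm separation (nn1-nn5).
#'
#' @param pitch_mm lattice constant in mm.
#' @param k number of classes to return.
#' @return numeric vector of length `k`, separations in mm.
#' @examples
#' neighbor_distance_classes(9.75, 5)  # fifth class rounds to 40 mm
#' @export
neighbor_distance_classes <- function(pitch_mm, k) {
  if (pitch_mm <= 0) stop("pitch_mm must be positive")
  if (k < 1) stop("k must be >= 1")
  # enumerate integer offsets with odd parity on a patch large enough for k
  n <- max(8L, ceiling(sqrt(2 * k)) + 4L)
  off <- expand.grid(i = -n:n, j = -n:n)
  off <- off[(abs(off$i) + abs(off$j)) %% 2 == 1, ]
  d2 <- sort(unique(off$i^2 + off$j^2))
  pitch_mm * sqrt(d2[seq_len(k)])
}

#' Enumerate source-detector channels within a separation cutoff
#'
#' All source-detector pairs of a grid with separation strictly below
#' `max_separation_mm`, tagged with their nearest-neighbour class (the rank of
#' the pair's distance class among the lattice's distinct distance classes)
#' and duplicated per wavelength.
#'
#' @param grid an [checkerboard_grid()] object (or any `optode_grid`).
#' @param max_separation_mm retain pairs with separation strictly less than
#'   this (mm). DOT systems conventionally use 40 mm: longer channels carry
#'   too little light.
#' @param wavelengths numeric vector of wavelength tags (nm); the channel list
#'   is identical for every wavelength.
#' @param class_tol_mm distances within this tolerance are binned into one
#'   class (guards floating-point lattice arithmetic).
#' @return object of class `channel_set`: data.frame with columns `channel_id`,
#'   `source_id`, `detector_id`, `separation_mm`, `nn_class`, `wavelength_nm`.
#' @export
enumerate_channels <- function(grid, max_separation_mm,
                               wavelengths = c(685, 830),
                               class_tol_mm = 0.5) {
  stopifnot(inherits(grid, "optode_grid"))
  pitch <- attr(grid, "pitch_mm")
  if (max_separation_mm <= pitch)
    stop("empty channel set: max_separation_mm must exceed the lattice pitch")
  src <- grid[grid$role == "source", ]
  det <- grid[grid$role == "detector", ]
  dx <- outer(src$x, det$x, "-")
  dy <- outer(src$y, det$y, "-")
  dz <- outer(src$z, det$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- which(d < max_separation_mm, arr.ind = TRUE)
  if (nrow(keep) == 0)
    stop("empty channel set: no source-detector pair below the cutoff")
  sep <- d[keep]
  ord <- order(sep, src$optode_id[keep[, 1]], det$optode_id[keep[, 2]])
  keep <- keep[ord, , drop = FALSE]
  sep <- sep[ord]
  # bin separations into distance classes with the stated tolerance
  cls <- integer(length(sep))
  cls[1] <- 1L
  ref <- sep[1]
  for (i in seq_along(sep)[-1]) {
    if (sep[i] - ref > class_tol_mm) {
      cls[i] <- cls[i - 1] + 1L
      ref <- sep[i]
    } else cls[i] <- cls[i - 1]
  }
  one <- data.frame(
    source_id = src$optode_id[keep[, 1]],
    detector_id = det$optode_id[keep[, 2]],
    separation_mm = sep,
    nn_class = cls,
    stringsAsFactors = FALSE
  )
  ch <- do.call(rbind, lapply(wavelengths, function(w)
    cbind(one, wavelength_nm = w)))
  ch$channel_id <- seq_len(nrow(ch))
  ch <- ch[, c("channel_id", "source_id", "detector_id", "separation_mm",
               "nn_class", "wavelength_nm")]
  class(ch) <- c("channel_set", "data.frame")
  attr(ch, "pitch_mm") <- pitch
  attr(ch, "max_separation_mm") <- max_separation_mm
  ch
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d channels (%d pairs x %d wavelengths), nn classes %s\n",
              nrow(x), nrow(x) / length(unique(x$wavelength_nm)),
              length(unique(x$wavelength_nm)),
              paste(sort(unique(x$nn_class)), collapse = ",")))
  invisible(x)
}

#' Align a grid to a reference map by iterative Dice matching
#'
#' Mirrors the light-model placement loop used when co-registering a DOT pad
#' against a reference functional map: candidate grid translations are tried
#' in order, the map is re-reconstructed for each, and the loop stops as soon
#' as the Dice overlap with the reference (both maps binarized at
#' `threshold_frac` of their own maximum) exceeds `dice_min`, or after
#' `max_iter` translations.
#'
#' @param candidate_translations list of length-3 numeric translations (mm),
#'   tried in order; the first candidate is typically c(0,0,0).
#' @param recon_map_fn function(translation) returning a numeric map (any
#'   shape) comparable with `reference_map`.
#' @param reference_map numeric array; must contain nonzero values.
#' @param threshold_frac binarization threshold as a fraction of each map's
#'   maximum (default 0.20).
#' @param dice_min stop as soon as Dice exceeds this (default 0.2).
#' @param max_iter maximum translations tried (default 5).
#' @return list with `translation`, `dice`, `iterations`, `converged`, and
#'   `history` (data.frame of per-iteration Dice).
#' @export
align_grid_by_dice <- function(candidate_translations, recon_map_fn,
                               reference_map, threshold_frac = 0.20,
                               dice_min = 0.2, max_iter = 5) {
  if (all(reference_map == 0)) stop("degenerate reference: map is all zeros")
  if (dice_min <= 0 || dice_min >= 1) stop("dice_min must be in (0,1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  n_try <- min(length(candidate_translations), max_iter)
  ref_bin <- reference_map >= threshold_frac * max(reference_map)
  best <- list(dice = -Inf)
  hist <- data.frame(iteration = integer(), dice = numeric())
  for (i in seq_len(n_try)) {
    tr <- candidate_translations[[i]]
    m <- recon_map_fn(tr)
    mx <- max(m)
    d <- if (mx <= 0) 0 else {
      b <- m >= threshold_frac * mx
      denom <- sum(b) + sum(ref_bin)
      if (denom == 0) 0 else 2 * sum(b & ref_bin) / denom
    }
    hist <- rbind(hist, data.frame(iteration = i, dice = d))
    if (d > best$dice) best <- list(dice = d, translation = tr, iteration = i)
    if (d > dice_min) {
      return(list(translation = tr, dice = d, iterations = i,
                  converged = TRUE, history = hist))
    }
  }
  warning("grid alignment did not reach the Dice criterion; returning best candidate")
  list(translation = best$translation, dice = best$dice, iterations = n_try,
       converged = FALSE, history = hist)
}
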