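# File-format adapters: SNIRF-schema JSON containers for channel data and
# probe geometry, NIfTI volumes for reconstructed images, TSV event tables,
# CSV channel tables.

#' Write a channel series and probe to a SNIRF-schema JSON container
#'
#' Serializes measurements and probe geometry using the SNIRF group/dataset
#' layout (nirs/data1/dataTimeSeries + measurementList, nirs/probe with
#' sourcePos3D/detectorPos3D/wavelengths), stored as JSON. The field names
#' and structure mirror the SNIRF specification so the probe and measurement
#' list round-trip losslessly.
#'
#' @param series a [dot_series()] or named list of them (one per wavelength);
#'   each must carry a channel table.
#' @param grid the `optode_grid` the channels refer to.
#' @param path output path (conventionally `.snirf.json`).
#' @return `path`, invisibly.
#' @export
write_snirf <- function(series, grid, path) {
  if (inherits(series, "dot_series")) series <- list(series)
  ch_all <- do.call(rbind, lapply(series, function(s) s$channels))
  if (is.null(ch_all)) stop("series must carry channel tables")
  src <- grid[grid$role == "source", ]
  det <- grid[grid$role == "detector", ]
  wls <- sort(unique(ch_all$wavelength_nm))
  ml <- lapply(seq_len(nrow(ch_all)), function(i) list(
    sourceIndex = match(ch_all$source_id[i], src$optode_id),
    detectorIndex = match(ch_all$detector_id[i], det$optode_id),
    wavelengthIndex = match(ch_all$wavelength_nm[i], wls),
    dataType = 1,
    dataTypeIndex = 1))
  Y <- do.call(rbind, lapply(series, function(s) s$values))
  fs <- series[[1]]$fs
  obj <- list(
    formatVersion = "1.0",
    nirs = list(
      data1 = list(
        dataTimeSeries = t(Y),              # SNIRF stores time x channels
        time = (seq_len(ncol(Y)) - 1) / fs,
        measurementList = ml),
      probe = list(
        wavelengths = wls,
        sourcePos3D = unname(as.matrix(src[, c("x", "y", "z")])),
        detectorPos3D = unname(as.matrix(det[, c("x", "y", "z")])),
        sourceLabels = paste0("S", seq_len(nrow(src))),
        detectorLabels = paste0("D", seq_len(nrow(det)))),
      metaDataTags = list(
        LengthUnit = "mm", TimeUnit = "s",
        DataUnit = series[[1]]$unit,
        pitch_mm = attr(grid, "pitch_mm"))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a SNIRF-schema JSON container
#'
#' @param path file written by [write_snirf()] (or any JSON file following
#'   the same SNIRF-style layout).
#' @return list with `series` (named list of [dot_series()], one per
#'   wavelength), `grid` (an `optode_grid`), `channels` (a `channel_set`).
#' @export
read_snirf <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$nirs))
    stop("format error: missing group /nirs")
  for (g in c("data1", "probe")) {
    if (is.null(obj$nirs[[g]]))
      stop("format error: missing group /nirs/", g)
  }
  probe <- obj$nirs$probe
  for (d in c("sourcePos3D", "detectorPos3D", "wavelengths")) {
    if (is.null(probe[[d]]))
      stop("format error: missing dataset /nirs/probe/", d)
  }
  data1 <- obj$nirs$data1
  if (is.null(data1$dataTimeSeries))
    stop("format error: missing dataset /nirs/data1/dataTimeSeries")
  src <- matrix(as.numeric(probe$sourcePos3D), ncol = 3)
  det <- matrix(as.numeric(probe$detectorPos3D), ncol = 3)
  pitch <- obj$nirs$metaDataTags$pitch_mm
  if (is.null(pitch)) pitch <- NA_real_
  g <- data.frame(
    optode_id = seq_len(nrow(src) + nrow(det)),
    x = c(src[, 1], det[, 1]), y = c(src[, 2], det[, 2]),
    z = c(src[, 3], det[, 3]),
    role = c(rep("source", nrow(src)), rep("detector", nrow(det))),
    panel = "P1", stringsAsFactors = FALSE)
  class(g) <- c("optode_grid", "data.frame")
  attr(g, "pitch_mm") <- pitch
  ml <- data1$measurementList
  wls <- as.numeric(probe$wavelengths)
  src_ids <- g$optode_id[g$role == "source"]
  det_ids <- g$optode_id[g$role == "detector"]
  ch <- data.frame(
    channel_id = seq_len(nrow(ml)),
    source_id = src_ids[ml$sourceIndex],
    detector_id = det_ids[ml$detectorIndex],
    wavelength_nm = wls[ml$wavelengthIndex])
  ch$separation_mm <- sqrt(
    (g$x[ch$source_id] - g$x[ch$detector_id])^2 +
    (g$y[ch$source_id] - g$y[ch$detector_id])^2 +
    (g$z[ch$source_id] - g$z[ch$detector_id])^2)
  # nn_class = rank of each channel's separation among the distinct classes
  seps <- sort(unique(round(ch$separation_mm, 6)))
  ch$nn_class <- findInterval(round(ch$separation_mm, 6), seps)
  class(ch) <- c("channel_set", "data.frame")
  Y <- t(matrix(as.numeric(data1$dataTimeSeries),
                ncol = nrow(ml)))
  tvec <- as.numeric(data1$time)
  fs <- if (length(tvec) > 1) 1 / stats::median(diff(tvec)) else 1
  unit <- obj$nirs$metaDataTags$DataUnit
  if (is.null(unit)) unit <- "log-ratio"
  series <- lapply(wls, function(w) {
    rows <- which(ch$wavelength_nm == w)
    dot_series(Y[rows, , drop = FALSE], fs = fs, unit = unit,
               channels = ch[rows, , drop = FALSE], wavelength_nm = w)
  })
  names(series) <- wls
  list(series = series, grid = g, channels = ch)
}

#' Write a voxel image as NIfTI
#'
#' The affine encodes the voxel spacing on its diagonal and the grid origin
#' in its translation column; multi-frame images use the 4th dimension.
#'
#' @param img a [voxel_image()].
#' @param path output `.nii` (or `.nii.gz`) path.
#' @return `path`, invisibly.
#' @export
write_voxel_nifti <- function(img, path) {
  stopifnot(inherits(img, "voxel_image"))
  ph <- img$phantom
  arr <- array(img$values, dim = c(ph$dims, ncol(img$values)))
  if (dim(arr)[4] == 1) arr <- arr[, , , 1]
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- rep(ph$voxel_mm, length(dim(arr)))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a NIfTI volume back onto a phantom grid
#'
#' @param path NIfTI file.
#' @param phantom the [slab_phantom()] the volume was written from.
#' @param unit unit tag for the result.
#' @return a [voxel_image()].
#' @export
read_voxel_nifti <- function(path, phantom, unit = "dmua_mm-1") {
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  if (!all(d[1:3] == phantom$dims))
    stop("volume dimensions do not match the phantom")
  nt <- if (length(d) >= 4) d[4] else 1
  voxel_image(matrix(as.numeric(arr), prod(phantom$dims), nt), phantom,
              unit = unit)
}

#' Read and write stimulus event tables as TSV
#'
#' Tab-separated `onset`, `duration`, `condition` columns (seconds), the
#' conventional exchange format for block/event designs.
#'
#' @param design a [stimulus_design()].
#' @param path TSV path.
#' @return `path` (write) or a [stimulus_design()] (read).
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "stimulus_design"))
  df <- as.data.frame(design)
  attr(df, "run_duration_s") <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  # run duration kept as a comment-free sidecar convention: last event end
  invisible(path)
}

#' @rdname write_events_tsv
#' @param run_duration_s run length; default: end of the last event.
#' @export
read_events_tsv <- function(path, run_duration_s = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(run_duration_s))
    run_duration_s <- max(df$onset + df$duration)
  stimulus_design(df$onset, df$duration, df$condition, run_duration_s)
}

#' Export a channel table as CSV
#'
#' @param channels a `channel_set`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_channels_csv <- function(channels, path) {
  utils::write.csv(as.data.frame(channels), path, row.names = FALSE)
  invisible(path)
}
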