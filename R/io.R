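#' @include AllClasses.R
NULL

#' Write a voxel stack as multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are ordered z-fastest within channel. Intensities are stored as
#' 16-bit integers after division by an integer quantum `q =
#' ceiling(max / 65535)` recorded in the sidecar, so integer-valued
#' stacks (photon counts) up to 65535 round-trip bit-identically. The
#' sidecar (`<path>.json`) carries voxel sizes, channel names, the
#' quantum, and an arbitrary truth record.
#'
#' @param stack 3-D (y, x, z) or 4-D (y, x, z, channel) array.
#' @param path output TIFF path.
#' @param voxelSizeXY,voxelSizeZ physical voxel sizes (micron).
#' @param channelNames character vector, one per channel.
#' @param truth optional list serialized losslessly into the sidecar.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, voxelSizeXY, voxelSizeZ,
                       channelNames = NULL, truth = NULL) {
  d <- dim(stack)
  if (length(d) == 3L) {
    stack <- array(stack, c(d, 1L))
    d <- dim(stack)
  }
  stopifnot(length(d) == 4L)
  if (is.null(channelNames))
    channelNames <- paste0("channel", seq_len(d[4]))
  q <- max(1, ceiling(max(stack, 0) / 65535))
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- round(stack[, , z, ch] / q) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(
    format = "poreQuant-stack", version = 1L,
    dim = as.integer(d), voxelSizeXY = voxelSizeXY,
    voxelSizeZ = voxelSizeZ, channels = channelNames,
    quantum = q, truth = truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a voxel stack written by [writeStack()]
#'
#' Reads the TIFF pages and the JSON sidecar. Without a sidecar, the
#' voxel sizes must be supplied via `voxelSizeXY` / `voxelSizeZ` (and
#' `nChannels`); otherwise a missing-calibration error is raised.
#'
#' @param path TIFF path.
#' @param voxelSizeXY,voxelSizeZ calibration override (micron).
#' @param nChannels channel-count override for sidecar-less files.
#' @return list with `stack` (4-D array), `voxelSizeXY`, `voxelSizeZ`,
#'   `channels`, and `truth` (list or `NULL`).
#' @export
readStack <- function(path, voxelSizeXY = NULL, voxelSizeZ = NULL,
                      nChannels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    q <- as.numeric(meta$quantum)
    vxy <- meta$voxelSizeXY; vz <- meta$voxelSizeZ
    channels <- meta$channels
    truth <- meta$truth
  } else {
    if (is.null(voxelSizeXY) || is.null(voxelSizeZ))
      stop("no calibration sidecar found for '", path,
           "' and no voxel-size override given")
    nc <- if (is.null(nChannels)) 1L else as.integer(nChannels)
    nz <- length(pages) / nc
    if (nz != floor(nz)) stop("page count not divisible by channel count")
    d <- c(dim(pages[[1]]), as.integer(nz), nc)
    q <- NA_real_
    vxy <- voxelSizeXY; vz <- voxelSizeZ
    channels <- paste0("channel", seq_len(nc))
    truth <- NULL
  }
  stack <- array(0, d)
  i <- 0L
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    i <- i + 1L
    plane <- pages[[i]] * 65535
    if (!is.na(q)) plane <- round(plane) * q
    stack[, , z, ch] <- plane
  }
  list(stack = stack, voxelSizeXY = vxy, voxelSizeZ = vz,
       channels = channels, truth = truth)
}

#' Write a scene's ground truth as a JSON sidecar record
#'
#' @param truth a truth list (e.g. from [sceneTruth()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a truth record written by [writeTruth()]
#'
#' @param path JSON path.
#' @return the truth list.
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
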