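#' @include AllClasses.R
NULL

#' Maximum intensity projection over a physical depth
#'
#' Per-pixel maximum over the z-planes spanning `depth`, centered on the
#' stack midplane. Germline stacks are conventionally projected over
#' 10 micron before cropping nuclei; shallower stacks use all planes.
#'
#' @param stack 3-D array (y, x, z) of one channel.
#' @param depth projection depth (micron); `NULL` projects all planes.
#' @param voxelSizeZ axial step (micron).
#' @return 2-D matrix of per-pixel maxima.
#' @examples
#' st <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
#' maxProject(st, depth = 1.5, voxelSizeZ = 0.5)
#' @export
maxProject <- function(stack, depth = NULL, voxelSizeZ = 0.5) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  nz <- d[3]
  if (is.null(depth)) {
    zi <- seq_len(nz)
  } else {
    nPlanes <- round(depth / voxelSizeZ)
    if (nPlanes > nz)
      stop("projection depth ", depth, " um exceeds stack depth ",
           nz * voxelSizeZ, " um")
    nPlanes <- max(1L, nPlanes)
    start <- floor((nz - nPlanes) / 2) + 1L
    zi <- start:(start + nPlanes - 1L)
  }
  out <- stack[, , zi[1]]
  for (k in zi[-1]) out <- pmax(out, stack[, , k])
  out
}

#' Crop the projected nucleus from a synthetic scene
#'
#' Projects the pore channel and crops the nucleus bounding box (envelope
#' radius plus a margin), mirroring the practice of cropping individual
#' nuclei before measuring the clustering index.
#'
#' @param scene a [SyntheticScene-class].
#' @param margin extra crop margin beyond the envelope radius (micron).
#' @param depth projection depth passed to [maxProject()].
#' @param channel channel to project (1 = pores).
#' @return a [NucleusImage-class] with crop provenance.
#' @export
cropSceneNucleus <- function(scene, margin = 0.2, depth = NULL,
                             channel = 1L) {
  stopifnot(is(scene, "SyntheticScene"))
  tr <- scene@truth
  vxy <- tr$optics$voxelSizeXY
  proj <- maxProject(scene@stack[, , , channel], depth = depth,
                     voxelSizeZ = tr$optics$voxelSizeZ)
  c0 <- scene@envelope@center
  R <- scene@envelope@radius + scene@envelope@shellThickness / 2 + margin
  rows <- max(1L, ceiling((c0[2] - R) / vxy)):
          min(nrow(proj), ceiling((c0[2] + R) / vxy))
  cols <- max(1L, ceiling((c0[1] - R) / vxy)):
          min(ncol(proj), ceiling((c0[1] + R) / vxy))
  NucleusImage(proj[rows, cols], pixelSizeXY = vxy,
               provenance = list(sourceSeed = tr$seed, channel = channel,
                                 rows = range(rows), cols = range(cols)))
}

#' Nuclear-pore clustering index of one nucleus
#'
#' The clustering index is the standard deviation of gray values over the
#' cropped nucleus: clustered pores concentrate photons into fewer, brighter
#' pixels, raising the intensity spread at fixed total signal. Population
#' (divide-by-n) SD is the default; sample SD is available via `type`.
#'
#' @param img a [NucleusImage-class] or a numeric matrix/array.
#' @param type `"population"` (default) or `"sample"`.
#' @return the raw clustering index (intensity units).
#' @examples
#' clusteringIndex(matrix(c(0, 0, 10, 10), 2))  # 5
#' @export
clusteringIndex <- function(img, type = c("population", "sample")) {
  type <- match.arg(type)
  v <- if (is(img, "NucleusImage")) as.numeric(img@pixels) else as.numeric(img)
  if (length(v) < 2L) stop("clustering index requires at least 2 pixels")
  if (anyNA(v)) stop("image contains NA pixels")
  m <- mean(v)
  ss <- sum((v - m)^2)
  sqrt(ss / if (type == "population") length(v) else (length(v) - 1L))
}

#' Normalize clustering indices to a control condition
#'
#' Divides every raw index by the mean of the control group so the control
#' group averages exactly 1.0; experimental conditions are then read as
#' fold change in clustering relative to control.
#'
#' @param values numeric raw indices.
#' @param groups group label per value.
#' @param control the control group label.
#' @return data.frame with `group`, `raw`, and `normalized`.
#' @export
normalizeToControl <- function(values, groups, control) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (!control %in% groups)
    stop("control group '", control, "' is empty")
  ctrlMean <- mean(values[groups == control])
  if (!is.finite(ctrlMean) || ctrlMean == 0)
    stop("control-group mean is zero; normalization undefined")
  data.frame(group = groups, raw = values,
             normalized = values / ctrlMean)
}

## ---------------------------------------------------------------------------
## Smoothing, Otsu, labeling
## ---------------------------------------------------------------------------

#' One pass of a 3 x 3 uniform mean filter
#'
#' Each pixel becomes the mean of its in-bounds 3 x 3 neighborhood (edge
#' pixels average over the 4 or 6 neighbors that exist). This is the
#' "smoothed once" step preceding Otsu segmentation.
#'
#' @param img numeric matrix.
#' @return smoothed matrix of the same shape.
#' @export
smoothOnce <- function(img) {
  img <- as.matrix(img)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    yt <- ys - dy; xt <- xs - dx
    acc[yt, xt] <- acc[yt, xt] + img[ys, xs]
    cnt[yt, xt] <- cnt[yt, xt] + 1
  }
  acc / cnt
}

#' Otsu threshold on a 256-bin histogram
#'
#' Bins the image's intensities into 256 equal-width bins spanning the
#' image's own range and returns the threshold maximizing the
#' between-class variance (first maximum on ties). Foreground is
#' `intensity > threshold`.
#'
#' @param img numeric matrix or vector of intensities.
#' @param nbins number of histogram bins (256 by convention).
#' @return the threshold (intensity units).
#' @export
otsuThreshold <- function(img, nbins = 256L) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi)
    stop("Otsu threshold undefined on a constant image")
  edges <- seq(lo, hi, length.out = nbins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * mids)
  total <- w0[nbins]; mTot <- m0[nbins]
  k <- seq_len(nbins - 1L)
  w1 <- total - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigmaB <- rep(-Inf, nbins - 1L)
  sigmaB[valid] <- (mTot * w0[k][valid] - m0[k][valid] * total)^2 /
    (w0[k][valid] * w1[valid])
  kStar <- which.max(sigmaB)
  edges[kStar + 1L]
}

#' 8-connected labeling of a binary mask
#'
#' Labels connected foreground components using 8-connectivity (diagonal
#' neighbors connect). Implemented by iterative label propagation to a
#' fixed point.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background), relabeled
#'   to consecutive integers in raster order of first occurrence.
#' @export
labelComponents <- function(mask) {
  mask <- as.matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  shiftM <- function(m, dy, dx) {
    out <- matrix(0L, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    out[ys - dy, xs - dx] <- m[ys, xs]
    out
  }
  repeat {
    nb <- lab
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- pmax(nb, shiftM(lab, dy, dx))
    }
    nb[!mask] <- 0L
    if (identical(nb, lab)) break
    lab <- nb
  }
  ## consecutive labels in order of first appearance
  ids <- unique(lab[lab > 0L])
  lab[] <- match(lab, c(0L, ids)) - 1L
  lab
}

#' Segment pore clusters from a cropped nucleus image
#'
#' Reproduces the standard cluster-area protocol: smooth once with a
#' 3 x 3 mean filter, threshold with Otsu's method on a 256-bin histogram
#' over the smoothed image's intensity range, label 8-connected
#' foreground components, and report per-cluster areas in square micron.
#' Components touching the crop border are excluded from the area list
#' (and recorded), mirroring the practice of avoiding clusters on the
#' edge of nuclei.
#'
#' @param img a [NucleusImage-class] with 2-D pixels, or a numeric matrix
#'   (then `pixelSizeXY` must be given).
#' @param pixelSizeXY lateral pixel size (micron) for matrix input.
#' @return a [ClusterSet-class].
#' @export
segmentClusters <- function(img, pixelSizeXY = NULL) {
  if (is(img, "NucleusImage")) {
    px <- img@pixels
    if (length(dim(px)) == 3L)
      stop("segmentClusters expects a 2-D projection; maxProject() first")
    m <- matrix(px, dim(px)[1], dim(px)[2])
    psz <- img@pixelSizeXY
  } else {
    m <- as.matrix(img)
    if (is.null(pixelSizeXY)) stop("pixelSizeXY required for matrix input")
    psz <- pixelSizeXY
  }
  sm <- smoothOnce(m)
  if (min(sm) == max(sm))
    stop("constant image after smoothing; Otsu segmentation undefined")
  thr <- otsuThreshold(sm)
  lab <- labelComponents(sm > thr)
  nLab <- max(lab)
  border <- integer()
  areasPx <- integer()
  if (nLab > 0L) {
    borderLabels <- unique(c(lab[1, ], lab[nrow(lab), ],
                             lab[, 1], lab[, ncol(lab)]))
    borderLabels <- borderLabels[borderLabels > 0L]
    counts <- tabulate(lab[lab > 0L], nLab)
    keep <- setdiff(seq_len(nLab), borderLabels)
    border <- as.integer(sort(borderLabels))
    areasPx <- counts[keep]
    names(areasPx) <- keep
  }
  areas <- areasPx * psz^2
  new("ClusterSet", labels = lab,
      areas = if (length(areas)) stats::setNames(as.numeric(areas),
                                                 names(areasPx))
              else numeric(),
      thresholdUsed = thr, excludedBorderLabels = border,
      pixelSizeXY = psz)
}

#' Total cluster area binned by cluster area
#'
#' For a set of per-cluster areas, sums the total area contributed by
#' clusters falling in each `[edge_i, edge_{i+1})` bin; also reports the
#' cluster count per bin (size-frequency view).
#'
#' @param areas numeric cluster areas (square micron); may pool several
#'   [ClusterSet-class] objects' areas.
#' @param binEdges strictly increasing bin edges (square micron).
#' @return data.frame with `binLow`, `binHigh`, `totalArea`, `count`.
#' @examples
#' clusterAreaHistogram(c(0.4, 0.6, 2.5), c(0, 0.5, 1, 3))
#' @export
clusterAreaHistogram <- function(areas, binEdges) {
  binEdges <- as.numeric(binEdges)
  if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
    stop("binEdges must be strictly increasing with >= 2 edges")
  areas <- as.numeric(areas)
  nb <- length(binEdges) - 1L
  idx <- findInterval(areas, binEdges)
  inRange <- idx >= 1L & idx <= nb & areas < binEdges[nb + 1L]
  totalArea <- numeric(nb)
  count <- integer(nb)
  if (any(inRange)) {
    tw <- tapply(areas[inRange], factor(idx[inRange], levels = seq_len(nb)),
                 sum)
    totalArea <- as.numeric(ifelse(is.na(tw), 0, tw))
    count <- as.integer(table(factor(idx[inRange], levels = seq_len(nb))))
  }
  data.frame(binLow = binEdges[-(nb + 1L)], binHigh = binEdges[-1L],
             totalArea = totalArea, count = count)
}
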