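#' @include AllClasses.R
NULL

#' Threshold a channel into a binary mask
#'
#' Foreground is `intensity > threshold`. The threshold comes either from
#' Otsu's method on the channel itself or from a fixed value; both the
#' method and the value are recorded on the mask for provenance.
#'
#' @param img numeric matrix (or 3-D array) of intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param value fixed threshold (required when `method = "fixed"`).
#' @param pixelSizeXY lateral pixel size (micron).
#' @return a [BinaryMask-class].
#' @examples
#' binarizeChannel(matrix(c(0, 40, 60), 1), method = "fixed", value = 50,
#'                 pixelSizeXY = 0.1)
#' @export
binarizeChannel <- function(img, method = c("otsu", "fixed"), value = NULL,
                            pixelSizeXY = 1) {
  method <- match.arg(method)
  a <- if (is.matrix(img)) array(img, dim(img)) else as.array(img)
  thr <- if (method == "otsu") otsuThreshold(a) else {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    as.numeric(value)
  }
  new("BinaryMask", pixels = array(a > thr, dim(a)),
      pixelSizeXY = as.numeric(pixelSizeXY),
      thresholdMethod = method, thresholdValue = thr)
}

#' Area of a reference mask overlapped by a second mask
#'
#' Applies the granule mask as a selection on the thresholded pore image:
#' the intersection area divided by the reference (pore) mask area gives
#' the coverage fraction. Works for 2-D or 3-D masks of identical shape.
#'
#' @param referenceMask a [BinaryMask-class] (e.g. the pore channel).
#' @param selectionMask a [BinaryMask-class] (e.g. the granule channel).
#' @return an [OverlapResult-class].
#' @export
overlapFraction <- function(referenceMask, selectionMask) {
  stopifnot(is(referenceMask, "BinaryMask"), is(selectionMask, "BinaryMask"))
  a <- referenceMask@pixels; b <- selectionMask@pixels
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape")
  if (abs(referenceMask@pixelSizeXY - selectionMask@pixelSizeXY) > 1e-12)
    stop("masks must share the same pixel size")
  nRef <- sum(a)
  if (nRef == 0L)
    stop("reference mask is empty; overlap fraction undefined")
  pxArea <- referenceMask@pixelSizeXY^2
  nInt <- sum(a & b)
  new("OverlapResult", referenceArea = nRef * pxArea,
      intersectArea = nInt * pxArea, fraction = nInt / nRef)
}

#' Fraction of large pore clusters covered by granules
#'
#' A cluster counts as covered when its label overlaps the granule mask in
#' at least `minOverlapPx` pixels (default 1: any overlap, the binary
#' scoring used for the large-cluster statistic). Only clusters with area
#' strictly greater than `areaThreshold` qualify.
#'
#' @param clusters a [ClusterSet-class].
#' @param granuleMask a [BinaryMask-class] co-registered with the cluster
#'   label image.
#' @param areaThreshold minimum qualifying cluster area (square micron),
#'   exclusive; the headline statistic uses 1.5.
#' @param minOverlapPx minimum overlapping pixel count to call a cluster
#'   covered.
#' @return list with `fraction` (covered / qualifying; `NA` when no
#'   cluster qualifies), `nCovered`, `nQualifying`, and `coveredLabels`.
#' @export
largeClusterCoverage <- function(clusters, granuleMask, areaThreshold = 1.5,
                                 minOverlapPx = 1L) {
  stopifnot(is(clusters, "ClusterSet"), is(granuleMask, "BinaryMask"))
  gm <- granuleMask@pixels
  if (!identical(dim(gm), dim(clusters@labels)))
    stop("granule mask and cluster labels must have identical shape")
  qual <- as.integer(names(clusters@areas)[clusters@areas > areaThreshold])
  if (!length(qual))
    return(list(fraction = NA_real_, nCovered = 0L, nQualifying = 0L,
                coveredLabels = integer()))
  lab <- clusters@labels
  ov <- tabulate(lab[gm & lab > 0L], max(lab))
  covered <- qual[ov[qual] >= minOverlapPx]
  list(fraction = length(covered) / length(qual),
       nCovered = length(covered), nQualifying = length(qual),
       coveredLabels = covered)
}

#' Center-of-mass distance between two labeled granules
#'
#' Intensity-weighted centroid of each granule in physical units, then the
#' Euclidean distance between the two centroids.
#'
#' @param intensityA,intensityB 3-D intensity arrays.
#' @param maskA,maskB logical 3-D arrays selecting each granule's voxels.
#' @param voxelSize numeric(3) voxel size (x, y, z) in micron.
#' @return list with `comA`, `comB` (micron, x/y/z) and `distance`
#'   (micron).
#' @export
comDistance <- function(intensityA, maskA, intensityB, maskB,
                        voxelSize = c(0.1, 0.1, 0.5)) {
  com <- function(intensity, mask) {
    d <- dim(intensity)
    stopifnot(length(d) == 3L, identical(d, dim(mask)))
    idx <- which(mask)
    if (!length(idx)) stop("empty granule label; center of mass undefined")
    w <- as.numeric(intensity[idx])
    if (sum(w) <= 0) stop("granule has zero total intensity")
    ai <- arrayInd(idx, d)
    ## array dims are (y, x, z); physical x from column, y from row
    px <- (ai[, 2] - 0.5) * voxelSize[1]
    py <- (ai[, 1] - 0.5) * voxelSize[2]
    pz <- (ai[, 3] - 0.5) * voxelSize[3]
    c(x = sum(w * px) / sum(w), y = sum(w * py) / sum(w),
      z = sum(w * pz) / sum(w))
  }
  a <- com(intensityA, maskA)
  b <- com(intensityB, maskB)
  list(comA = a, comB = b, distance = sqrt(sum((a - b)^2)))
}

#' Count foci in a single imaging plane
#'
#' Automated surrogate for manual focus counting: the plane is smoothed
#' with a Gaussian of sigma `spotSigma`, and strict local maxima over the
#' 8-neighborhood whose smoothed amplitude exceeds the image median by at
#' least `prominence` are counted. Two spots closer than the smoothing
#' scale merge into one detected maximum (documented behavior).
#'
#' @param plane numeric matrix (single z-plane).
#' @param spotSigma Gaussian smoothing sigma in pixels.
#' @param prominence minimum height above the plane's median intensity.
#' @return list with `count` and `peaks` (n x 2 matrix of row/col
#'   positions).
#' @export
countFociPlane <- function(plane, spotSigma = 1.5, prominence = 10) {
  m <- as.matrix(plane)
  nr <- nrow(m); nc <- ncol(m)
  sm <- gaussSmooth2(m, spotSigma)
  shiftM <- function(x, dy, dx, fill = -Inf) {
    out <- matrix(fill, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    out[ys - dy, xs - dx] <- x[ys, xs]
    out
  }
  isMax <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & sm > shiftM(sm, dy, dx)
  }
  isMax <- isMax & sm >= stats::median(sm) + prominence
  isMax[c(1, nr), ] <- FALSE
  isMax[, c(1, nc)] <- FALSE
  peaks <- which(isMax, arr.ind = TRUE)
  list(count = nrow(peaks), peaks = peaks)
}

## 2-D Gaussian smoothing, separable, edge-renormalized.
gaussSmooth2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm((-hw):hw, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x, margin) {
    n <- dim(x)[margin]
    out <- array(0, dim(x)); wsum <- array(0, dim(x))
    for (i in seq_along(k)) {
      off <- i - hw - 1L
      src <- seq_len(n - abs(off))
      if (off > 0) { to <- src + off } else { to <- src; src <- src - off }
      if (margin == 1L) {
        out[to, ] <- out[to, ] + k[i] * x[src, ]
        wsum[to, ] <- wsum[to, ] + k[i]
      } else {
        out[, to] <- out[, to] + k[i] * x[, src]
        wsum[, to] <- wsum[, to] + k[i]
      }
    }
    out / wsum
  }
  smooth1(smooth1(m, 1L), 2L)
}

#' Fraction of granule area inside the rachis
#'
#' Binarizes the granule channel over the germline region and reports the
#' granule area lying in the rachis (central shared cytoplasm) divided by
#' the granule area of the whole germline (rachis plus nuclear rim
#' region). The rachis and nuclei masks must be disjoint.
#'
#' @param plane numeric matrix, single central slice of the granule
#'   channel.
#' @param rachisMask,nucleiMask logical matrices partitioning the
#'   germline.
#' @param method,value thresholding as in [binarizeChannel()].
#' @return list with `fraction` (`NA` when no granule pixels exist),
#'   `rachisArea`, `totalArea` (pixel counts).
#' @export
rachisGranuleFraction <- function(plane, rachisMask, nucleiMask,
                                  method = c("otsu", "fixed"),
                                  value = NULL) {
  method <- match.arg(method)
  rachisMask <- as.matrix(rachisMask); nucleiMask <- as.matrix(nucleiMask)
  if (any(rachisMask & nucleiMask))
    stop("rachis and nuclei masks must be disjoint")
  germline <- rachisMask | nucleiMask
  gm <- binarizeChannel(plane, method = method, value = value)@pixels
  gm <- matrix(gm, nrow(gm), ncol(gm))
  inRachis <- sum(gm & rachisMask)
  total <- sum(gm & germline)
  if (total == 0L)
    return(list(fraction = NA_real_, rachisArea = 0L, totalArea = 0L))
  list(fraction = inRachis / total, rachisArea = inRachis,
       totalArea = total)
}

#' Measure granule coverage of pore clusters on a rendered scene
#'
#' End-to-end measurement used to validate coverage recovery: projects the
#' pore channel, segments pore clusters (smooth + Otsu + 8-connected
#' components), binarizes the granule channel, and scores each qualifying
#' cluster as covered or not via [largeClusterCoverage()].
#'
#' @param scene a [SyntheticScene-class].
#' @param areaThreshold qualifying cluster area (square micron,
#'   exclusive).
#' @param minOverlapPx covered-cluster criterion, in pixels.
#' @param granuleMethod,granuleValue granule-channel thresholding; the
#'   default fixed threshold is placed above the optics background level.
#' @param projectionDepth depth for the pore-channel projection (micron).
#' @return list as returned by [largeClusterCoverage()] plus `clusters`
#'   and `granuleMask`.
#' @export
measureSceneCoverage <- function(scene, areaThreshold = 0.3,
                                 minOverlapPx = 1L,
                                 granuleMethod = c("fixed", "otsu"),
                                 granuleValue = NULL,
                                 projectionDepth = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  granuleMethod <- match.arg(granuleMethod)
  tr <- scene@truth
  vxy <- tr$optics$voxelSizeXY; vz <- tr$optics$voxelSizeZ
  poreProj <- maxProject(scene@stack[, , , 1L], depth = projectionDepth,
                         voxelSizeZ = vz)
  granProj <- maxProject(scene@stack[, , , 2L], depth = projectionDepth,
                         voxelSizeZ = vz)
  cs <- segmentClusters(poreProj, pixelSizeXY = vxy)
  if (granuleMethod == "fixed" && is.null(granuleValue)) {
    bg <- tr$optics$backgroundLevel
    granuleValue <- bg + 5 * sqrt(max(bg, 1)) + 3 * tr$optics$readNoiseSD
  }
  gm <- binarizeChannel(granProj, method = granuleMethod,
                        value = granuleValue, pixelSizeXY = vxy)
  res <- largeClusterCoverage(cs, gm, areaThreshold = areaThreshold,
                              minOverlapPx = minOverlapPx)
  res$clusters <- cs
  res$granuleMask <- gm
  res
}
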