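#' @import methods
NULL

## ---------------------------------------------------------------------------
## Synthetic-scene parameter classes
## ---------------------------------------------------------------------------

#' Idealized spherical nuclear envelope
#'
#' Geometry of a single nucleus modeled as a spherical shell. Pachytene
#' germline nuclei are close to spherical; pores live on (or within a thin
#' shell around) the envelope surface.
#'
#' @slot center numeric(3), envelope center in physical coordinates (micron).
#' @slot radius envelope radius (micron), strictly positive.
#' @slot shellThickness radial thickness of the shell band that may hold
#'   pore centers (micron); points are placed within `shellThickness / 2`
#'   of the sphere surface.
#'
#' @examples
#' env <- EnvelopeModel(radius = 2.5)
#' envelopeRadius(env)
#' @export
setClass("EnvelopeModel",
  representation(center = "numeric", radius = "numeric",
                 shellThickness = "numeric"))

setValidity("EnvelopeModel", function(object) {
  msg <- character()
  if (length(object@center) != 3L || anyNA(object@center))
    msg <- c(msg, "center must be a numeric 3-vector")
  if (length(object@radius) != 1L || is.na(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(object@shellThickness) != 1L || is.na(object@shellThickness) ||
      object@shellThickness < 0 || object@shellThickness >= object@radius)
    msg <- c(msg, "shellThickness must satisfy 0 <= shellThickness < radius")
  if (length(msg)) msg else TRUE
})

#' @param center numeric(3) envelope center (micron).
#' @param radius envelope radius (micron).
#' @param shellThickness shell band thickness (micron).
#' @rdname EnvelopeModel-class
#' @export
EnvelopeModel <- function(center = c(0, 0, 0), radius = 2.5,
                          shellThickness = 0.1) {
  new("EnvelopeModel", center = as.numeric(center),
      radius = as.numeric(radius),
      shellThickness = as.numeric(shellThickness))
}

#' Parameters of the clustered pore point process
#'
#' Pores are placed by a Matern-style parent/offspring process on the
#' envelope sphere: parent directions are uniform on the sphere and
#' offspring directions follow a von Mises-Fisher kernel around their
#' parent with concentration `offspringConcentration`. A concentration of
#' zero degenerates to uniform sampling over the whole sphere. A fraction
#' `uniformFraction` of pores is always placed uniformly, independent of
#' the parents, emulating the dispersed individual pores seen between
#' clusters.
#'
#' @slot nPores total number of pores.
#' @slot nParents number of cluster parents.
#' @slot offspringConcentration von Mises-Fisher concentration (kappa,
#'   dimensionless, >= 0) of offspring around parents; 0 means uniform.
#' @slot uniformFraction fraction in [0, 1] of pores placed uniformly
#'   regardless of parents (labeled 0 in the output).
#'
#' @examples
#' ClusterProcessParams(nPores = 150, nParents = 6,
#'                      offspringConcentration = 20)
#' @export
setClass("ClusterProcessParams",
  representation(nPores = "integer", nParents = "integer",
                 offspringConcentration = "numeric",
                 uniformFraction = "numeric"))

setValidity("ClusterProcessParams", function(object) {
  msg <- character()
  if (object@nPores < 0L) msg <- c(msg, "nPores must be >= 0")
  if (object@offspringConcentration < 0)
    msg <- c(msg, "offspringConcentration must be >= 0")
  if (object@offspringConcentration > 0 && object@nParents < 1L)
    msg <- c(msg, "nParents must be >= 1 when offspringConcentration > 0")
  if (object@uniformFraction < 0 || object@uniformFraction > 1)
    msg <- c(msg, "uniformFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param nPores,nParents,offspringConcentration,uniformFraction see slots.
#' @rdname ClusterProcessParams-class
#' @export
ClusterProcessParams <- function(nPores = 200, nParents = 8,
                                 offspringConcentration = 20,
                                 uniformFraction = 0.25) {
  new("ClusterProcessParams", nPores = as.integer(nPores),
      nParents = as.integer(nParents),
      offspringConcentration = as.numeric(offspringConcentration),
      uniformFraction = as.numeric(uniformFraction))
}

#' Parameters of perinuclear granule caps
#'
#' Granules are modeled as solid spherical-cap shells sitting on the
#' cytoplasmic face of the envelope, each (approximately) centered over a
#' pore cluster. `capOffsetJitter` perturbs the cap center away from the
#' cluster center, reproducing the imperfect registration between pore
#' clusters and overlying granules.
#'
#' @slot coverageFraction fraction in [0, 1] of pore clusters that receive
#'   an overlying granule cap.
#' @slot capAngularRadius angular radius of each cap (radians, > 0).
#' @slot capOffsetJitter standard deviation of the angular offset between
#'   cluster center and cap center (radians, >= 0).
#' @slot intensityScale total photon budget per cap.
#' @slot capThickness radial thickness of the cap shell (micron).
#'
#' @export
setClass("GranuleParams",
  representation(coverageFraction = "numeric", capAngularRadius = "numeric",
                 capOffsetJitter = "numeric", intensityScale = "numeric",
                 capThickness = "numeric"))

setValidity("GranuleParams", function(object) {
  msg <- character()
  if (object@coverageFraction < 0 || object@coverageFraction > 1)
    msg <- c(msg, "coverageFraction must lie in [0, 1]")
  if (object@capAngularRadius <= 0)
    msg <- c(msg, "capAngularRadius must be > 0")
  if (object@capOffsetJitter < 0)
    msg <- c(msg, "capOffsetJitter must be >= 0")
  if (object@intensityScale < 0)
    msg <- c(msg, "intensityScale must be >= 0")
  if (object@capThickness <= 0)
    msg <- c(msg, "capThickness must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param coverageFraction,capAngularRadius,capOffsetJitter,intensityScale,capThickness
#'   see slots.
#' @rdname GranuleParams-class
#' @export
GranuleParams <- function(coverageFraction = 1, capAngularRadius = 0.35,
                          capOffsetJitter = 0.05, intensityScale = 20000,
                          capThickness = 0.4) {
  new("GranuleParams", coverageFraction = as.numeric(coverageFraction),
      capAngularRadius = as.numeric(capAngularRadius),
      capOffsetJitter = as.numeric(capOffsetJitter),
      intensityScale = as.numeric(intensityScale),
      capThickness = as.numeric(capThickness))
}

#' Image-formation parameters
#'
#' Voxel geometry, point-spread function, photon budget and noise of the
#' simulated microscope. Defaults follow high-resolution germline imaging:
#' 8 micron stacks at 0.5 micron z-step. The PSF is a separable
#' anisotropic Gaussian; noise is Poisson shot noise on signal plus
#' background, with additive Gaussian read noise, both optional.
#'
#' @slot voxelSizeXY lateral voxel size (micron).
#' @slot voxelSizeZ axial voxel size / z-step (micron).
#' @slot psfSigmaXY lateral PSF Gaussian sigma (micron).
#' @slot psfSigmaZ axial PSF Gaussian sigma (micron).
#' @slot backgroundLevel constant background (photons per voxel, >= 0).
#' @slot photonsPerPunctum integrated photon budget of one pore punctum.
#' @slot readNoiseSD Gaussian read-noise standard deviation (photons, >= 0).
#' @slot stackDepth physical depth of the stack (micron).
#' @slot fieldWidth lateral field width (micron); `NA` sizes the field
#'   automatically around the envelope.
#'
#' @export
setClass("OpticsParams",
  representation(voxelSizeXY = "numeric", voxelSizeZ = "numeric",
                 psfSigmaXY = "numeric", psfSigmaZ = "numeric",
                 backgroundLevel = "numeric", photonsPerPunctum = "numeric",
                 readNoiseSD = "numeric", stackDepth = "numeric",
                 fieldWidth = "numeric"))

setValidity("OpticsParams", function(object) {
  msg <- character()
  pos <- c(voxelSizeXY = object@voxelSizeXY, voxelSizeZ = object@voxelSizeZ,
           psfSigmaXY = object@psfSigmaXY, psfSigmaZ = object@psfSigmaZ,
           photonsPerPunctum = object@photonsPerPunctum,
           stackDepth = object@stackDepth)
  bad <- names(pos)[!is.na(pos) & pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0(paste(bad, collapse = ", "),
                         " must be strictly positive"))
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  if (object@readNoiseSD < 0) msg <- c(msg, "readNoiseSD must be >= 0")
  if (!is.na(object@fieldWidth) && object@fieldWidth <= 0)
    msg <- c(msg, "fieldWidth must be positive (or NA for automatic)")
  if (length(msg)) msg else TRUE
})

#' @param voxelSizeXY,voxelSizeZ,psfSigmaXY,psfSigmaZ,backgroundLevel
#'   see slots.
#' @param photonsPerPunctum,readNoiseSD,stackDepth,fieldWidth see slots.
#' @rdname OpticsParams-class
#' @export
OpticsParams <- function(voxelSizeXY = 0.1, voxelSizeZ = 0.5,
                         psfSigmaXY = 0.12, psfSigmaZ = 0.35,
                         backgroundLevel = 10, photonsPerPunctum = 500,
                         readNoiseSD = 2, stackDepth = 8,
                         fieldWidth = NA_real_) {
  new("OpticsParams", voxelSizeXY = as.numeric(voxelSizeXY),
      voxelSizeZ = as.numeric(voxelSizeZ),
      psfSigmaXY = as.numeric(psfSigmaXY),
      psfSigmaZ = as.numeric(psfSigmaZ),
      backgroundLevel = as.numeric(backgroundLevel),
      photonsPerPunctum = as.numeric(photonsPerPunctum),
      readNoiseSD = as.numeric(readNoiseSD),
      stackDepth = as.numeric(stackDepth),
      fieldWidth = as.numeric(fieldWidth))
}

#' Parameters of the synthetic FISH field generator
#'
#' A two-channel 2-D field emulating a target transcript channel and a
#' control transcript channel sharing the same background. Optional bright
#' disk-shaped granule regions boost the target channel only.
#'
#' @slot targetMean mean target-channel signal per pixel (above background).
#' @slot controlMean mean control-channel signal per pixel (> 0).
#' @slot backgroundMean shared background per pixel (>= 0).
#' @slot granuleBoost multiplicative boost of the target signal inside
#'   granule regions (1 = none).
#' @slot fieldShape integer(2), field size in pixels (rows, columns).
#' @slot nGranules number of granule disks.
#' @slot granuleRadius granule disk radius (pixels).
#'
#' @export
setClass("FishFieldParams",
  representation(targetMean = "numeric", controlMean = "numeric",
                 backgroundMean = "numeric", granuleBoost = "numeric",
                 fieldShape = "integer", nGranules = "integer",
                 granuleRadius = "numeric"))

setValidity("FishFieldParams", function(object) {
  msg <- character()
  if (object@targetMean < 0) msg <- c(msg, "targetMean must be >= 0")
  if (object@controlMean <= 0)
    msg <- c(msg, "controlMean must be > 0 (control transcript present)")
  if (object@backgroundMean < 0) msg <- c(msg, "backgroundMean must be >= 0")
  if (object@granuleBoost < 0) msg <- c(msg, "granuleBoost must be >= 0")
  if (length(object@fieldShape) != 2L || any(object@fieldShape < 1L))
    msg <- c(msg, "fieldShape must be two positive integers")
  if (length(msg)) msg else TRUE
})

#' @param targetMean,controlMean,backgroundMean,granuleBoost,fieldShape
#'   see slots.
#' @param nGranules,granuleRadius see slots.
#' @rdname FishFieldParams-class
#' @export
FishFieldParams <- function(targetMean = 50, controlMean = 50,
                            backgroundMean = 20, granuleBoost = 1,
                            fieldShape = c(96L, 96L), nGranules = 0,
                            granuleRadius = 4) {
  new("FishFieldParams", targetMean = as.numeric(targetMean),
      controlMean = as.numeric(controlMean),
      backgroundMean = as.numeric(backgroundMean),
      granuleBoost = as.numeric(granuleBoost),
      fieldShape = as.integer(fieldShape),
      nGranules = as.integer(nGranules),
      granuleRadius = as.numeric(granuleRadius))
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Ground-truth-annotated synthetic scene
#'
#' One simulated nucleus: pore positions with cluster labels, granule cap
#' geometry, the rendered two-channel voxel stack, and a truth record
#' holding every generator parameter. Channel 1 of the stack is the pore
#' channel, channel 2 the granule channel. Stack dimensions are
#' (y, x, z, channel); the physical position of voxel center (i, j, k) is
#' ((j - 0.5) vxy, (i - 0.5) vxy, (k - 0.5) vz) in (x, y, z).
#'
#' @slot porePoints numeric matrix (n x 3) of pore centers (x, y, z,
#'   micron).
#' @slot clusterLabels integer(n); parent index per pore, 0 for pores
#'   placed uniformly.
#' @slot granuleCaps numeric matrix (k x 4): unit cap-center direction
#'   (x, y, z) and angular radius (radians) per cap.
#' @slot stack 4-D array (y, x, z, channel) of nonnegative intensities.
#' @slot envelope the [EnvelopeModel-class] the scene was built on.
#' @slot truth named list of all generator parameters and derived truth
#'   (covered cluster indices, photon budgets, seeds).
#'
#' @export
setClass("SyntheticScene",
  representation(porePoints = "matrix", clusterLabels = "integer",
                 granuleCaps = "matrix", stack = "array",
                 envelope = "EnvelopeModel", truth = "list"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (ncol(object@porePoints) != 3L && nrow(object@porePoints) > 0L)
    msg <- c(msg, "porePoints must have 3 columns")
  if (nrow(object@porePoints) != length(object@clusterLabels))
    msg <- c(msg, "one cluster label per pore point required")
  if (length(dim(object@stack)) != 4L)
    msg <- c(msg, "stack must be a 4-D (y, x, z, channel) array")
  if (nrow(object@porePoints) > 0L) {
    d <- sqrt(colSums((t(object@porePoints) - object@envelope@center)^2))
    tol <- object@envelope@shellThickness / 2 + 1e-9
    if (any(abs(d - object@envelope@radius) > tol))
      msg <- c(msg, "pore points must lie within the envelope shell")
  }
  if (length(msg)) msg else TRUE
})

#' Cropped single-nucleus image
#'
#' A 2-D projection or 3-D sub-stack of one nucleus with its physical
#' pixel sizes and provenance (source id, crop bounds, projection depth).
#' The crop is assumed to exclude neighboring nuclei; that is the caller's
#' contract, mirroring manual cropping practice.
#'
#' @slot pixels 2-D matrix or 3-D array of nonnegative intensities.
#' @slot pixelSizeXY lateral pixel size (micron, > 0).
#' @slot voxelSizeZ axial step for 3-D pixels (micron; `NA` for 2-D).
#' @slot provenance named list (source id, crop bounds, notes).
#'
#' @export
setClass("NucleusImage",
  representation(pixels = "array", pixelSizeXY = "numeric",
                 voxelSizeZ = "numeric", provenance = "list"))

setValidity("NucleusImage", function(object) {
  msg <- character()
  nd <- length(dim(object@pixels))
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "pixels must be a 2-D matrix or 3-D array")
  if (is.na(object@pixelSizeXY) || object@pixelSizeXY <= 0)
    msg <- c(msg, "pixelSizeXY must be > 0")
  if (nd == 3L && (is.na(object@voxelSizeZ) || object@voxelSizeZ <= 0))
    msg <- c(msg, "voxelSizeZ must be > 0 for a 3-D sub-stack")
  if (length(msg)) msg else TRUE
})

#' @param pixels 2-D matrix or 3-D array of intensities.
#' @param pixelSizeXY lateral pixel size (micron).
#' @param voxelSizeZ axial step (micron) for 3-D input.
#' @param provenance named list recording where the crop came from.
#' @rdname NucleusImage-class
#' @export
NucleusImage <- function(pixels, pixelSizeXY, voxelSizeZ = NA_real_,
                         provenance = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  new("NucleusImage", pixels = pixels,
      pixelSizeXY = as.numeric(pixelSizeXY),
      voxelSizeZ = as.numeric(voxelSizeZ), provenance = provenance)
}

#' Segmented pore-cluster set
#'
#' Labeled connected components of a thresholded pore image with
#' per-cluster areas in square micron. Components touching the crop border
#' are excluded from `areas` and listed in `excludedBorderLabels`,
#' mirroring the practice of avoiding clusters on the edge of nuclei.
#' Label 0 is background.
#'
#' @slot labels integer label matrix, same shape as the segmented image.
#' @slot areas numeric vector of areas (square micron) of non-border
#'   clusters, named by label.
#' @slot thresholdUsed the Otsu threshold applied (intensity units).
#' @slot excludedBorderLabels integer labels of border-touching components.
#' @slot pixelSizeXY lateral pixel size (micron).
#'
#' @export
setClass("ClusterSet",
  representation(labels = "matrix", areas = "numeric",
                 thresholdUsed = "numeric",
                 excludedBorderLabels = "integer", pixelSizeXY = "numeric"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (length(object@areas) && any(object@areas <= 0))
    msg <- c(msg, "all areas must be > 0")
  cropArea <- prod(dim(object@labels)) * object@pixelSizeXY^2
  if (sum(object@areas) > cropArea + 1e-9)
    msg <- c(msg, "total cluster area cannot exceed the crop area")
  if (length(msg)) msg else TRUE
})

#' Thresholded channel mask
#'
#' Boolean foreground mask of one channel plus the provenance of the
#' threshold that produced it.
#'
#' @slot pixels logical 2-D matrix or 3-D array.
#' @slot pixelSizeXY lateral pixel size (micron).
#' @slot thresholdMethod `"otsu"` or `"fixed"`.
#' @slot thresholdValue the threshold applied (intensity units).
#'
#' @export
setClass("BinaryMask",
  representation(pixels = "array", pixelSizeXY = "numeric",
                 thresholdMethod = "character", thresholdValue = "numeric"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels))
    msg <- c(msg, "mask pixels must be logical")
  if (is.na(object@pixelSizeXY) || object@pixelSizeXY <= 0)
    msg <- c(msg, "pixelSizeXY must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pore/granule overlap measurement for one nucleus
#'
#' Area of the reference (pore) mask, the area of its intersection with
#' the granule mask, and the resulting coverage fraction.
#'
#' @slot referenceArea reference-mask area (square micron).
#' @slot intersectArea intersection area (square micron).
#' @slot fraction `intersectArea / referenceArea`, in [0, 1].
#'
#' @export
setClass("OverlapResult",
  representation(referenceArea = "numeric", intersectArea = "numeric",
                 fraction = "numeric"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@intersectArea < -1e-12 ||
      object@intersectArea > object@referenceArea + 1e-9)
    msg <- c(msg, "0 <= intersectArea <= referenceArea violated")
  f <- object@intersectArea / object@referenceArea
  if (abs(f - object@fraction) > 1e-9)
    msg <- c(msg, "fraction must equal intersectArea / referenceArea")
  if (length(msg)) msg else TRUE
})

#' Ordered pore centers along an EM cross-section
#'
#' One-dimensional pore-center positions digitized along the nuclear
#' envelope contour of an electron-microscopy cross-section. Pores are
#' identified from membrane fusion sites with a characteristic diameter
#' of roughly 100-120 nm; `poreDiameter` records the convention used.
#'
#' @slot positions strictly increasing numeric positions (micron).
#' @slot poreDiameter pore-diameter convention (nanometer).
#'
#' @export
setClass("PoreProfile",
  representation(positions = "numeric", poreDiameter = "numeric"))

setValidity("PoreProfile", function(object) {
  msg <- character()
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (anyNA(object@positions)) msg <- c(msg, "positions must not be NA")
  if (length(msg)) msg else TRUE
})

#' @param positions numeric pore-center positions (micron); sorted
#'   internally.
#' @param poreDiameter pore-diameter convention (nanometer).
#' @rdname PoreProfile-class
#' @export
PoreProfile <- function(positions = numeric(), poreDiameter = 110) {
  p <- sort(as.numeric(positions))
  if (anyDuplicated(p))
    stop("duplicate pore positions are not a valid profile")
  new("PoreProfile", positions = p, poreDiameter = as.numeric(poreDiameter))
}
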