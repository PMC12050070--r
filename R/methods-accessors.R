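#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases envelopeRadius,EnvelopeModel-method
setMethod("envelopeRadius", "EnvelopeModel", function(object) object@radius)

#' @rdname accessors
setMethod("porePoints", "SyntheticScene", function(object) object@porePoints)

#' @rdname accessors
setMethod("clusterLabels", "SyntheticScene",
          function(object) object@clusterLabels)

#' @rdname accessors
setMethod("granuleCaps", "SyntheticScene", function(object) object@granuleCaps)

#' @rdname accessors
setMethod("sceneStack", "SyntheticScene", function(object) object@stack)

#' @rdname accessors
setMethod("sceneTruth", "SyntheticScene", function(object) object@truth)

#' @rdname accessors
setMethod("pixels", "NucleusImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) == 2L) p <- matrix(p, nrow(p), ncol(p))
  p
})

#' @rdname accessors
setMethod("pixels", "BinaryMask", function(object) {
  p <- object@pixels
  if (length(dim(p)) == 2L) p <- matrix(as.logical(p), nrow(p), ncol(p))
  p
})

#' @rdname accessors
setMethod("pixelSizeXY", "NucleusImage", function(object) object@pixelSizeXY)

#' @rdname accessors
setMethod("pixelSizeXY", "BinaryMask", function(object) object@pixelSizeXY)

#' @rdname accessors
setMethod("pixelSizeXY", "ClusterSet", function(object) object@pixelSizeXY)

#' @rdname accessors
setMethod("clusterAreas", "ClusterSet", function(object) object@areas)

#' @rdname accessors
setMethod("labelImage", "ClusterSet", function(object) object@labels)

#' @rdname accessors
setMethod("thresholdUsed", "ClusterSet", function(object) object@thresholdUsed)

#' @rdname accessors
setMethod("thresholdUsed", "BinaryMask",
          function(object) object@thresholdValue)

#' @rdname accessors
setMethod("excludedBorderLabels", "ClusterSet",
          function(object) object@excludedBorderLabels)

#' @rdname accessors
setMethod("overlapFractionValue", "OverlapResult",
          function(object) object@fraction)

#' @rdname accessors
setMethod("referenceArea", "OverlapResult",
          function(object) object@referenceArea)

#' @rdname accessors
setMethod("intersectArea", "OverlapResult",
          function(object) object@intersectArea)

#' @rdname accessors
setMethod("porePositions", "PoreProfile", function(object) object@positions)

## show methods -------------------------------------------------------------

setMethod("show", "EnvelopeModel", function(object) {
  cat("EnvelopeModel: radius", object@radius, "um, shell",
      object@shellThickness, "um, center (",
      paste(signif(object@center, 4), collapse = ", "), ")\n")
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@stack)
  cat("SyntheticScene\n",
      " pores      : ", nrow(object@porePoints), " (",
      length(unique(object@clusterLabels[object@clusterLabels > 0L])),
      " clusters, ", sum(object@clusterLabels == 0L), " dispersed)\n",
      " granules   : ", nrow(object@granuleCaps), " caps\n",
      " stack      : ", d[1], " x ", d[2], " x ", d[3], " voxels, ",
      d[4], " channels\n", sep = "")
})

setMethod("show", "NucleusImage", function(object) {
  d <- dim(object@pixels)
  cat("NucleusImage: ", paste(d, collapse = " x "), " px, ",
      object@pixelSizeXY, " um/px\n", sep = "")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet: ", length(object@areas), " clusters (",
      length(object@excludedBorderLabels), " border-excluded), ",
      "threshold ", signif(object@thresholdUsed, 5), "\n", sep = "")
  if (length(object@areas))
    cat("  areas (um^2): ",
        paste(signif(sort(object@areas, decreasing = TRUE)[
          seq_len(min(6L, length(object@areas)))], 3), collapse = ", "),
        if (length(object@areas) > 6L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: reference %.3f um^2, intersect %.3f um^2, fraction %.3f\n",
    object@referenceArea, object@intersectArea, object@fraction))
})

setMethod("show", "PoreProfile", function(object) {
  n <- length(object@positions)
  cat("PoreProfile: ", n, " pores", sep = "")
  if (n > 1L)
    cat(sprintf(" over %.3g um (mean gap %.3g um)",
                diff(range(object@positions)),
                mean(diff(object@positions))))
  cat("\n")
})
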