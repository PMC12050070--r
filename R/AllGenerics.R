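#' @include AllClasses.R
NULL

#' Accessors for poreQuant objects
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object a poreQuant S4 object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("envelopeRadius", function(object) standardGeneric("envelopeRadius"))

#' @rdname accessors
#' @export
setGeneric("porePoints", function(object) standardGeneric("porePoints"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("granuleCaps", function(object) standardGeneric("granuleCaps"))

#' @rdname accessors
#' @export
setGeneric("sceneStack", function(object) standardGeneric("sceneStack"))

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeXY", function(object) standardGeneric("pixelSizeXY"))

#' @rdname accessors
#' @export
setGeneric("clusterAreas", function(object) standardGeneric("clusterAreas"))

#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))

#' @rdname accessors
#' @export
setGeneric("excludedBorderLabels",
           function(object) standardGeneric("excludedBorderLabels"))

#' @rdname accessors
#' @export
setGeneric("overlapFractionValue",
           function(object) standardGeneric("overlapFractionValue"))

#' @rdname accessors
#' @export
setGeneric("referenceArea", function(object) standardGeneric("referenceArea"))

#' @rdname accessors
#' @export
setGeneric("intersectArea", function(object) standardGeneric("intersectArea"))

#' @rdname accessors
#' @export
setGeneric("porePositions", function(object) standardGeneric("porePositions"))
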