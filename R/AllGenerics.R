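#' @include AllClasses.R
NULL

#' Accessors for retMosaic classes
#'
#' Small accessor generics exposing slots of the package's S4 classes;
#' user code should use these rather than \code{@}.
#'
#' @param object an S4 object from this package.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("sideLength", function(object) standardGeneric("sideLength"))

#' @rdname accessors
#' @export
setGeneric("pixelsPerSide", function(object) standardGeneric("pixelsPerSide"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("scheme", function(object) standardGeneric("scheme"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))

#' @rdname accessors
#' @export
setGeneric("dPR", function(object) standardGeneric("dPR"))

#' @rdname accessors
#' @export
setGeneric("ringFrequency", function(object) standardGeneric("ringFrequency"))

#' @rdname accessors
#' @export
setGeneric("ringQuality", function(object) standardGeneric("ringQuality"))

#' @rdname accessors
#' @export
setGeneric("isReliable", function(object) standardGeneric("isReliable"))

#' @rdname accessors
#' @export
setGeneric("marp", function(object) standardGeneric("marp"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("testUsed", function(object) standardGeneric("testUsed"))

#' Compute the maximum anatomical resolving power
#'
#' @param spacing a [SpacingEstimate-class] or a positive numeric spacing
#'   in micrometres.
#' @param eye an [EyeModel-class].
#' @return A [MarpResult-class].
#' @export
setGeneric("computeMarp", function(spacing, eye = EyeModel())
  standardGeneric("computeMarp"))
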