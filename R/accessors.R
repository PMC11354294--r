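#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("pixelSize", "FieldGeometry", function(object)
  object@sideLength / object@pixelsPerSide)

#' @rdname accessors
setMethod("pixelSize", "MosaicImage", function(object)
  pixelSize(object@geometry))

#' @rdname accessors
setMethod("sideLength", "FieldGeometry", function(object) object@sideLength)

#' @rdname accessors
setMethod("sideLength", "MosaicImage", function(object)
  object@geometry@sideLength)

#' @rdname accessors
setMethod("pixelsPerSide", "FieldGeometry", function(object)
  object@pixelsPerSide)

#' @rdname accessors
setMethod("pixelsPerSide", "MosaicImage", function(object)
  object@geometry@pixelsPerSide)

#' @rdname accessors
setMethod("intensities", "MosaicImage", function(object) object@intensities)

#' @rdname accessors
setMethod("geometry", "MosaicImage", function(object) object@geometry)

#' @rdname accessors
setMethod("scheme", "MosaicImage", function(object) object@scheme)

#' @rdname accessors
setMethod("groupLabel", "MosaicImage", function(object) object@group)

#' @rdname accessors
setMethod("groundTruth", "MosaicImage", function(object) object@groundTruth)

#' @rdname accessors
setMethod("labelMatrix", "LabelMap", function(object) object@labels)

#' @rdname accessors
setMethod("nCells", "LabelMap", function(object) object@nCells)

#' @rdname accessors
setMethod("maskMatrix", "BinaryMask", function(object) object@mask)

#' @rdname accessors
setMethod("thresholdValue", "BinaryMask", function(object)
  object@thresholdValue)

#' @rdname accessors
setMethod("dPR", "SpacingEstimate", function(object) object@dPR)

#' @rdname accessors
setMethod("dPR", "MarpResult", function(object) object@spacing@dPR)

#' @rdname accessors
setMethod("ringFrequency", "SpacingEstimate", function(object)
  object@ringFrequency)

#' @rdname accessors
setMethod("ringQuality", "SpacingEstimate", function(object) object@quality)

#' @rdname accessors
setMethod("isReliable", "SpacingEstimate", function(object) object@reliable)

#' @rdname accessors
setMethod("marp", "MarpResult", function(object) object@marp)

#' @rdname accessors
setMethod("pValue", "ComparisonResult", function(object) object@pValue)

#' @rdname accessors
setMethod("testUsed", "ComparisonResult", function(object) object@testUsed)

setMethod("show", "FieldGeometry", function(object) {
  cat(sprintf("FieldGeometry: %.6g x %.6g um, %d x %d px (%.4f um/px)\n",
              object@sideLength, object@sideLength, object@pixelsPerSide,
              object@pixelsPerSide, pixelSize(object)))
})

setMethod("show", "SamplingScheme", function(object) {
  cat(sprintf("SamplingScheme: quadrant %s, location #%d (step %.6g um)\n",
              object@quadrant, object@locationIndex, object@eccentricityStep))
})

setMethod("show", "GroupProfile", function(object) {
  cat(sprintf(
    paste0("GroupProfile [%s]: density %.6g /mm^2, area %.4g +/- %.3g um^2",
           " (CV %.3g)\n  inflamed fraction %.3g (ratio %.3g),",
           " lattice jitter %.3g\n"),
    object@group, object@targetDensity, object@meanArea,
    object@betweenSampleSD, object@withinAreaCV, object@inflamedFraction,
    object@inflamedAreaRatio, object@latticeJitter))
})

setMethod("show", "MosaicImage", function(object) {
  cat(sprintf("MosaicImage [%s] %s #%d: %d x %d px over %.6g um",
              object@group, object@scheme@quadrant,
              object@scheme@locationIndex, nrow(object@intensities),
              ncol(object@intensities), sideLength(object)))
  if (nrow(object@groundTruth) > 0)
    cat(sprintf(", %d ground-truth cells", nrow(object@groundTruth)))
  cat("\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask (%s): threshold %.6g, foreground fraction %.4f\n",
              object@method, object@thresholdValue, mean(object@mask)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d cells (%s seeds)\n", object@nCells,
              object@seedMode))
})

setMethod("show", "SpacingEstimate", function(object) {
  cat(sprintf("SpacingEstimate: D_PR = %.4g um (ring %.4g cycles/um, quality %.3g%s)\n",
              object@dPR, object@ringFrequency, object@quality,
              if (object@reliable) "" else ", UNRELIABLE"))
})

setMethod("show", "MarpResult", function(object) {
  cat(sprintf("MarpResult: %.4g cycles/deg (D_PR %.4g um, PND %.4g mm)\n",
              object@marp, object@spacing@dPR,
              object@eye@posteriorNodalDistance))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult: %s, statistic %.4g, p = %.4g (%ssignificant at 0.05)\n",
    object@testUsed, object@statistic, object@pValue,
    if (object@significant) "" else "not "))
  cat(sprintf("  n = %d vs %d; normality p = %.3g, %.3g\n", object@n[1],
              object@n[2], object@normalityP[1], object@normalityP[2]))
})
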