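#' @import methods
NULL

#' Field geometry of a scanned mosaic image
#'
#' Physical geometry of one scanned field: the side length of the (square)
#' field in micrometres and the raster size in pixels. The pixel pitch is
#' derived as \code{sideLength / pixelsPerSide} and is exposed through
#' \code{\link{pixelSize}}.
#'
#' @slot sideLength numeric(1), field side in micrometres (> 0).
#' @slot pixelsPerSide integer(1), raster side in pixels (>= 64).
#'
#' @seealso [FieldGeometry()] for the user constructor.
#' @export
setClass("FieldGeometry",
  representation(sideLength = "numeric", pixelsPerSide = "integer"),
  prototype(sideLength = 90, pixelsPerSide = 512L)
)

setValidity("FieldGeometry", function(object) {
  msg <- character()
  if (length(object@sideLength) != 1L || !is.finite(object@sideLength) ||
      object@sideLength <= 0)
    msg <- c(msg, "sideLength must be a single positive number (um)")
  if (length(object@pixelsPerSide) != 1L || is.na(object@pixelsPerSide) ||
      object@pixelsPerSide < 64L)
    msg <- c(msg, "pixelsPerSide must be a single integer >= 64")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldGeometry
#'
#' @param sideLength field side in micrometres; the instrument scans a
#'   square field of 90 x 90 um by default.
#' @param pixelsPerSide raster side in pixels (default 512, i.e. a pixel
#'   pitch of about 0.176 um).
#' @return A [FieldGeometry-class] object.
#' @examples
#' geom <- FieldGeometry()
#' pixelSize(geom)
#' @export
FieldGeometry <- function(sideLength = 90, pixelsPerSide = 512L) {
  new("FieldGeometry", sideLength = as.numeric(sideLength),
      pixelsPerSide = as.integer(pixelsPerSide))
}

#' Retinal sampling position of one image
#'
#' Identifies where on the flat-mounted retina an image was taken: one of
#' the four quadrants cut during whole-mounting (superior/inferior x
#' temporal/nasal) and one of four eccentricity locations numbered outward
#' from the optic nerve head, nominally equi-spaced by 540 um.
#'
#' @slot quadrant character(1), one of "ST", "SN", "IT", "IN".
#' @slot locationIndex integer(1) in 1..4 (1 = paracentral, 4 = peripheral).
#' @slot eccentricityStep numeric(1), spacing between locations in um.
#' @export
setClass("SamplingScheme",
  representation(quadrant = "character", locationIndex = "integer",
                 eccentricityStep = "numeric"),
  prototype(quadrant = "ST", locationIndex = 1L, eccentricityStep = 540)
)

setValidity("SamplingScheme", function(object) {
  msg <- character()
  if (!object@quadrant %in% c("ST", "SN", "IT", "IN"))
    msg <- c(msg, "quadrant must be one of ST, SN, IT, IN")
  if (!object@locationIndex %in% 1:4)
    msg <- c(msg, "locationIndex must be in 1..4")
  if (object@eccentricityStep <= 0)
    msg <- c(msg, "eccentricityStep must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SamplingScheme-class
#' @param quadrant,locationIndex,eccentricityStep see slots.
#' @export
SamplingScheme <- function(quadrant = "ST", locationIndex = 1L,
                           eccentricityStep = 540) {
  new("SamplingScheme", quadrant = as.character(quadrant),
      locationIndex = as.integer(locationIndex),
      eccentricityStep = as.numeric(eccentricityStep))
}

#' Generative profile of an experimental group
#'
#' Parameters of the synthetic-mosaic generator for one experimental group
#' (control or diabetic): target planar cell density, the transversal-area
#' distribution (between-retina mean and SD, within-image coefficient of
#' variation), the inflamed mixture component and the lattice disorder.
#'
#' The area model is a two-component lognormal mixture. A sample-level mean
#' \eqn{m} is drawn once per mosaic from Normal(meanArea, betweenSampleSD).
#' A fraction \code{inflamedFraction} of cells is flagged inflamed and drawn
#' around \code{inflamedAreaRatio} times the healthy component mean, which is
#' rescaled so the overall mosaic mean stays at \eqn{m}.
#'
#' @slot group character(1), "control" or "diabetic".
#' @slot targetDensity numeric(1), cells per mm^2.
#' @slot meanArea numeric(1), group mean transversal area, um^2.
#' @slot betweenSampleSD numeric(1), SD of per-mosaic mean areas, um^2.
#' @slot withinAreaCV numeric(1), per-cell coefficient of variation.
#' @slot inflamedFraction numeric(1) in [0, 1].
#' @slot inflamedAreaRatio numeric(1) > 0, inflamed / healthy mean ratio.
#' @slot latticeJitter numeric(1) in [0, 0.5), Gaussian displacement SD as a
#'   proportion of the nominal lattice spacing.
#' @seealso [controlProfile()], [diabeticProfile()]
#' @export
setClass("GroupProfile",
  representation(group = "character", targetDensity = "numeric",
                 meanArea = "numeric", betweenSampleSD = "numeric",
                 withinAreaCV = "numeric", inflamedFraction = "numeric",
                 inflamedAreaRatio = "numeric", latticeJitter = "numeric")
)

setValidity("GroupProfile", function(object) {
  msg <- character()
  if (!object@group %in% c("control", "diabetic"))
    msg <- c(msg, "group must be 'control' or 'diabetic'")
  if (object@targetDensity <= 0) msg <- c(msg, "targetDensity must be > 0")
  if (object@meanArea <= 0) msg <- c(msg, "meanArea must be > 0")
  if (object@betweenSampleSD < 0) msg <- c(msg, "betweenSampleSD must be >= 0")
  if (object@withinAreaCV < 0) msg <- c(msg, "withinAreaCV must be >= 0")
  if (object@inflamedFraction < 0 || object@inflamedFraction > 1)
    msg <- c(msg, "inflamedFraction must lie in [0, 1]")
  if (object@inflamedAreaRatio <= 0)
    msg <- c(msg, "inflamedAreaRatio must be > 0")
  if (object@latticeJitter < 0 || object@latticeJitter >= 0.5)
    msg <- c(msg, "latticeJitter must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Group generator profiles calibrated to the study groups
#'
#' `controlProfile()` and `diabeticProfile()` return [GroupProfile-class]
#' objects whose defaults are the published group summaries: mean
#' transversal areas of 10.04 +/- 0.42 um^2 (control) and 14.82 +/- 1.49
#' um^2 (diabetic), and the example densities of 43,951 and 33,210
#' cells/mm^2. Within-image CV, inflamed mixture and lattice jitter are
#' generator choices documented in the methods vignette.
#'
#' @param targetDensity cells per mm^2.
#' @param meanArea,betweenSampleSD um^2.
#' @param withinAreaCV per-cell area coefficient of variation.
#' @param inflamedFraction proportion of cells in the inflamed component.
#' @param inflamedAreaRatio inflamed / healthy component mean ratio.
#' @param latticeJitter proportion of the nominal spacing.
#' @return A [GroupProfile-class].
#' @examples
#' controlProfile()
#' diabeticProfile(inflamedFraction = 0.8)
#' @export
controlProfile <- function(targetDensity = 43951, meanArea = 10.04,
                           betweenSampleSD = 0.42, withinAreaCV = 0.15,
                           inflamedFraction = 0, inflamedAreaRatio = 1.5,
                           latticeJitter = 0.12) {
  new("GroupProfile", group = "control", targetDensity = targetDensity,
      meanArea = meanArea, betweenSampleSD = betweenSampleSD,
      withinAreaCV = withinAreaCV, inflamedFraction = inflamedFraction,
      inflamedAreaRatio = inflamedAreaRatio, latticeJitter = latticeJitter)
}

#' @rdname controlProfile
#' @export
diabeticProfile <- function(targetDensity = 33210, meanArea = 14.82,
                            betweenSampleSD = 1.49, withinAreaCV = 0.15,
                            inflamedFraction = 0.6, inflamedAreaRatio = 1.5,
                            latticeJitter = 0.12) {
  new("GroupProfile", group = "diabetic", targetDensity = targetDensity,
      meanArea = meanArea, betweenSampleSD = betweenSampleSD,
      withinAreaCV = withinAreaCV, inflamedFraction = inflamedFraction,
      inflamedAreaRatio = inflamedAreaRatio, latticeJitter = latticeJitter)
}

#' A single-channel mosaic intensity image with physical metadata
#'
#' Carrier for one two-photon-like intensity image of the photoreceptor
#' mosaic: the raster (rows = y, columns = x, non-negative intensities), its
#' [FieldGeometry-class], the retinal [SamplingScheme-class], the group
#' label, and — for synthetic images — the ground-truth cell table.
#'
#' @slot intensities numeric matrix, pixelsPerSide x pixelsPerSide, >= 0.
#' @slot geometry a [FieldGeometry-class].
#' @slot scheme a [SamplingScheme-class].
#' @slot group character(1), "control", "diabetic" or "unknown".
#' @slot groundTruth data.frame with columns cellId, x, y (um), trueArea
#'   (um^2), inflamed (logical); zero rows when the truth is unknown.
#' @slot seed integer(1), RNG seed the image was generated with (NA for
#'   external images).
#' @export
setClass("MosaicImage",
  representation(intensities = "matrix", geometry = "FieldGeometry",
                 scheme = "SamplingScheme", group = "character",
                 groundTruth = "data.frame", seed = "integer")
)

setValidity("MosaicImage", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  n <- object@geometry@pixelsPerSide
  if (d[1] != n || d[2] != n)
    msg <- c(msg, sprintf("intensities must be %d x %d to match geometry", n, n))
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@group %in% c("control", "diabetic", "unknown"))
    msg <- c(msg, "group must be control, diabetic or unknown")
  gt <- object@groundTruth
  if (nrow(gt) > 0 &&
      !all(c("cellId", "x", "y", "trueArea", "inflamed") %in% names(gt)))
    msg <- c(msg, "groundTruth needs columns cellId, x, y, trueArea, inflamed")
  if (length(msg)) msg else TRUE
})

emptyGroundTruth <- function() {
  data.frame(cellId = integer(), x = numeric(), y = numeric(),
             trueArea = numeric(), inflamed = logical())
}

#' @rdname MosaicImage-class
#' @param intensities,geometry,scheme,group,groundTruth,seed see slots.
#' @export
MosaicImage <- function(intensities, geometry = FieldGeometry(),
                        scheme = SamplingScheme(), group = "unknown",
                        groundTruth = emptyGroundTruth(), seed = NA_integer_) {
  new("MosaicImage", intensities = intensities, geometry = geometry,
      scheme = scheme, group = group, groundTruth = groundTruth,
      seed = as.integer(seed))
}

#' Binarized foreground mask of a mosaic image
#'
#' @slot mask logical matrix, TRUE on foreground (intensity >= threshold).
#' @slot thresholdValue numeric(1), the threshold actually applied.
#' @slot method character(1), "otsu", "fixed" or "percentile".
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", thresholdValue = "numeric",
                 method = "character")
)

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!object@method %in% c("otsu", "fixed", "percentile"))
    msg <- c(msg, "method must be otsu, fixed or percentile")
  if (length(msg)) msg else TRUE
})

#' Integer-labelled segmentation of a mosaic image
#'
#' Labels 1..K identify cells; 0 is background (including the one-pixel
#' watershed lines separating touching cells).
#'
#' @slot labels integer matrix, values in 0..K.
#' @slot nCells integer(1), K.
#' @slot seedMode character(1), "auto", "provided" or "distance".
#' @slot parameters list of run parameters (threshold used, smoothing, ...).
#' @export
setClass("LabelMap",
  representation(labels = "matrix", nCells = "integer",
                 seedMode = "character", parameters = "list")
)

setValidity("LabelMap", function(object) {
  msg <- character()
  K <- object@nCells
  lab <- object@labels
  if (any(lab < 0)) msg <- c(msg, "labels must be non-negative")
  if (K > 0) {
    cnt <- tabulate(lab[lab > 0L], nbins = K)
    if (any(cnt == 0L))
      msg <- c(msg, "every label in 1..K must occupy at least one pixel")
    if (max(lab) > K) msg <- c(msg, "labels exceed nCells")
  } else if (any(lab > 0)) {
    msg <- c(msg, "nCells = 0 but positive labels present")
  }
  if (length(msg)) msg else TRUE
})

#' Radially averaged Fourier power spectrum
#'
#' Mean power in annular frequency bins of width one frequency sample
#' (1/sideLength cycles/um), from DC to the raster Nyquist frequency.
#'
#' @slot frequencies numeric, bin-centre spatial frequencies (cycles/um),
#'   strictly increasing from 0.
#' @slot power numeric, mean power per bin (>= 0).
#' @slot counts integer, number of spectrum pixels averaged per bin.
#' @slot window character(1), "hann" or "none".
#' @slot dcExcludedRadius numeric(1), lower frequency bound recommended for
#'   peak searches (cycles/um).
#' @export
setClass("RadialSpectrum",
  representation(frequencies = "numeric", power = "numeric",
                 counts = "integer", window = "character",
                 dcExcludedRadius = "numeric")
)

setValidity("RadialSpectrum", function(object) {
  msg <- character()
  if (any(diff(object@frequencies) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(object@power) != length(object@frequencies) ||
      length(object@counts) != length(object@frequencies))
    msg <- c(msg, "frequencies, power and counts must have equal length")
  if (length(msg)) msg else TRUE
})

#' Inter-cell spacing estimated from the Yellott ring
#'
#' @slot dPR numeric(1), estimated inter-centre photoreceptor distance, um.
#' @slot ringFrequency numeric(1), ring radius in cycles/um.
#' @slot quality numeric(1), ring-peak power over local spectral background.
#' @slot reliable logical(1), FALSE when the peak does not clear the
#'   quality gate.
#' @export
setClass("SpacingEstimate",
  representation(dPR = "numeric", ringFrequency = "numeric",
                 quality = "numeric", reliable = "logical")
)

setValidity("SpacingEstimate", function(object) {
  msg <- character()
  if (object@dPR <= 0) msg <- c(msg, "dPR must be positive")
  if (object@ringFrequency <= 0)
    msg <- c(msg, "ringFrequency must be positive")
  if (length(msg)) msg else TRUE
})

#' Schematic eye model used for anatomical resolving power
#'
#' The conversion from retinal distance to visual angle uses the posterior
#' nodal distance (PND) of the schematic rat eye, 3.405 mm, a degrees-per-
#' radian constant fixed at 57.3 (kept at the published precision rather
#' than 180/pi) and the sqrt(3) Nyquist factor of a hexagonal mosaic.
#'
#' @slot posteriorNodalDistance numeric(1), mm.
#' @slot degreesPerRadian numeric(1), fixed 57.3.
#' @slot hexNyquistFactor numeric(1), sqrt(3).
#' @export
setClass("EyeModel",
  representation(posteriorNodalDistance = "numeric",
                 degreesPerRadian = "numeric", hexNyquistFactor = "numeric"),
  prototype(posteriorNodalDistance = 3.405, degreesPerRadian = 57.3,
            hexNyquistFactor = sqrt(3))
)

setValidity("EyeModel", function(object) {
  if (object@posteriorNodalDistance <= 0)
    "posteriorNodalDistance must be positive" else TRUE
})

#' @rdname EyeModel-class
#' @param posteriorNodalDistance posterior nodal distance in mm.
#' @export
EyeModel <- function(posteriorNodalDistance = 3.405) {
  new("EyeModel", posteriorNodalDistance = posteriorNodalDistance)
}

#' Maximum anatomical resolving power of a mosaic
#'
#' @slot marp numeric(1), cycles per degree.
#' @slot spacing the [SpacingEstimate-class] it was derived from.
#' @slot eye the [EyeModel-class] used.
#' @export
setClass("MarpResult",
  representation(marp = "numeric", spacing = "SpacingEstimate",
                 eye = "EyeModel")
)

#' Result of a two-group statistical comparison
#'
#' Produced by [compareGroups()] applying the study's decision rule:
#' Lilliefors-corrected Kolmogorov-Smirnov normality checks on both samples;
#' Student's t when both pass at alpha = 0.05, Mann-Whitney U otherwise.
#'
#' @slot testUsed character(1): "paired_t", "student_t" or "mann_whitney_u".
#' @slot statistic numeric(1), the test statistic.
#' @slot pValue numeric(1), two-sided.
#' @slot normalityP numeric(2), Lilliefors p for each sample.
#' @slot n integer(2), sample sizes.
#' @slot significant logical(1), pValue < 0.05.
#' @slot paired logical(1), pairing as requested by the caller.
#' @export
setClass("ComparisonResult",
  representation(testUsed = "character", statistic = "numeric",
                 pValue = "numeric", normalityP = "numeric", n = "integer",
                 significant = "logical", paired = "logical")
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!object@testUsed %in% c("paired_t", "student_t", "mann_whitney_u"))
    msg <- c(msg, "testUsed must be paired_t, student_t or mann_whitney_u")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@significant != (object@pValue < 0.05))
    msg <- c(msg, "significant must equal pValue < 0.05")
  if (length(msg)) msg else TRUE
})
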