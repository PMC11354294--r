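#' @include AllClasses.R
NULL

#' Planar cell density
#'
#' Count of segmented cells (border-touching cells included — they are
#' real cells) divided by the field area.
#'
#' @param measurements data.frame from [measureCells()], or anything with
#'   one row per cell.
#' @param fieldArea field area in mm^2 (a 90 x 90 um field is 0.0081 mm^2).
#' @return cells per mm^2.
#' @examples
#' cellDensity(data.frame(cellId = 1:356), 0.0081)  # ~43951
#' @export
cellDensity <- function(measurements, fieldArea) {
  stopifnotScalarPositive(fieldArea, "fieldArea")
  nrow(measurements) / fieldArea
}

#' Transversal-area summary statistics
#'
#' Arithmetic mean and sample SD of the measured transversal areas, after
#' optionally dropping border-touching cells. With a single cell the SD is
#' reported as 0 and flagged (`sdDefined = FALSE`).
#'
#' @param measurements data.frame with columns `area` and `touchesBorder`.
#' @param excludeBorder drop border-touching cells first (default TRUE).
#' @return list(mean, sd, n, sdDefined).
#' @export
areaStats <- function(measurements, excludeBorder = TRUE) {
  a <- cellAreas(measurements, excludeBorder)
  if (length(a) == 0)
    stop("no cells left to summarise", call. = FALSE)
  if (length(a) == 1L)
    return(list(mean = a, sd = 0, n = 1L, sdDefined = FALSE))
  list(mean = mean(a), sd = stats::sd(a), n = length(a), sdDefined = TRUE)
}

cellAreas <- function(measurements, excludeBorder = TRUE) {
  if (is.numeric(measurements)) return(measurements)
  a <- measurements$area
  if (is.null(a)) stop("measurements must have an `area` column",
                       call. = FALSE)
  if (excludeBorder && !is.null(measurements$touchesBorder))
    a <- a[!measurements$touchesBorder]
  a
}

#' Neuroinflammation count fraction
#'
#' Percentage of cells whose transversal area is strictly larger than the
#' healthy threshold (default 10 um^2, the control grand-mean area); a cell
#' exactly at the threshold counts as healthy.
#'
#' @param measurements data.frame with an `area` column, or a numeric
#'   vector of areas (um^2).
#' @param healthyThreshold um^2.
#' @param excludeBorder drop border-touching cells first (default TRUE).
#' @return percentage in [0, 100].
#' @examples
#' inflamedCountFraction(c(8, 9, 11, 12, 15))  # 60
#' @export
inflamedCountFraction <- function(measurements, healthyThreshold = 10,
                                  excludeBorder = TRUE) {
  stopifnotScalarPositive(healthyThreshold, "healthyThreshold")
  a <- cellAreas(measurements, excludeBorder)
  if (length(a) == 0) stop("no cells to classify", call. = FALSE)
  100 * sum(a > healthyThreshold) / length(a)
}

#' Neuroinflammation area fraction
#'
#' Total transversal area of cells above the healthy threshold divided by
#' the total area occupied by all cells, as a percentage: the portion of
#' photoreceptor-covered area affected by neuroinflammation.
#'
#' @inheritParams inflamedCountFraction
#' @return percentage in [0, 100].
#' @examples
#' inflamedAreaFraction(c(8, 9, 11, 12, 15))  # 100 * 38 / 55
#' @export
inflamedAreaFraction <- function(measurements, healthyThreshold = 10,
                                 excludeBorder = TRUE) {
  stopifnotScalarPositive(healthyThreshold, "healthyThreshold")
  a <- cellAreas(measurements, excludeBorder)
  if (length(a) == 0 || sum(a) <= 0)
    stop("total cell area must be positive", call. = FALSE)
  100 * sum(a[a > healthyThreshold]) / sum(a)
}

#' Percent increase of the diabetic over the control mean area
#'
#' @param controlMean,diabeticMean um^2.
#' @return 100 * (diabeticMean - controlMean) / controlMean.
#' @examples
#' percentIncrease(10.04, 14.82)  # 47.6 -> "48% on average"
#' @export
percentIncrease <- function(controlMean, diabeticMean) {
  stopifnotScalarPositive(controlMean, "controlMean")
  100 * (diabeticMean - controlMean) / controlMean
}

#' Per-image mosaic metrics
#'
#' Computes the full metric set for one segmented image: density (all
#' cells), area mean/SD and the two inflammation fractions (border cells
#' excluded), and cell count, tagged with the image's group/quadrant/
#' location metadata.
#'
#' @param measurements data.frame from [measureCells()] with border cells
#'   included.
#' @param geometry the image's [FieldGeometry-class].
#' @param healthyThreshold um^2 (default 10).
#' @param group,quadrant,locationIndex metadata columns; taken from
#'   `image` when supplied.
#' @param image optional [MosaicImage-class] supplying the metadata.
#' @return One-row data.frame: group, quadrant, locationIndex, nCells,
#'   density, meanArea, sdArea, inflamedCountFraction,
#'   inflamedAreaFraction.
#' @export
mosaicMetrics <- function(measurements, geometry, healthyThreshold = 10,
                          group = "unknown", quadrant = "ST",
                          locationIndex = 1L, image = NULL) {
  if (!is.null(image)) {
    geometry <- methods::slot(image, "geometry")
    group <- groupLabel(image)
    quadrant <- scheme(image)@quadrant
    locationIndex <- scheme(image)@locationIndex
  }
  fieldArea <- (sideLength(geometry) * 1e-3)^2
  inner <- measurements[!measurements$touchesBorder, , drop = FALSE]
  st <- if (nrow(inner) > 0) areaStats(inner, excludeBorder = FALSE)
        else list(mean = NA_real_, sd = NA_real_, n = 0L)
  data.frame(
    group = group, quadrant = quadrant, locationIndex = locationIndex,
    nCells = nrow(measurements),
    density = cellDensity(measurements, fieldArea),
    meanArea = st$mean, sdArea = st$sd,
    inflamedCountFraction = if (nrow(inner) > 0)
      inflamedCountFraction(inner, healthyThreshold) else NA_real_,
    inflamedAreaFraction = if (nrow(inner) > 0)
      inflamedAreaFraction(inner, healthyThreshold) else NA_real_)
}

#' Aggregate per-image metrics into grouped summaries
#'
#' Mean and SD of each metric within groups defined by any subset of
#' {group, locationIndex, quadrant}; row order follows the sorted key
#' values, so the result is invariant to the input ordering.
#'
#' @param metrics data.frame of per-image rows from [mosaicMetrics()].
#' @param keys character subset of c("group", "locationIndex", "quadrant").
#' @param values metric columns to summarise.
#' @return data.frame with the key columns, `n`, and `<value>_mean` /
#'   `<value>_sd` columns.
#' @export
aggregateMetrics <- function(metrics, keys = "group",
                             values = c("density", "meanArea",
                                        "inflamedCountFraction",
                                        "inflamedAreaFraction")) {
  allowed <- c("group", "locationIndex", "quadrant")
  bad <- setdiff(keys, allowed)
  if (length(bad))
    stop("unknown grouping key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  if (nrow(metrics) == 0) stop("empty metrics collection", call. = FALSE)
  values <- intersect(values, names(metrics))
  key <- interaction(metrics[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(metrics)), key)
  rows <- lapply(idx, function(i) {
    out <- metrics[i[1], keys, drop = FALSE]
    out$n <- length(i)
    for (v in values) {
      x <- metrics[[v]][i]
      out[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- if (sum(!is.na(x)) > 1)
        stats::sd(x, na.rm = TRUE) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
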