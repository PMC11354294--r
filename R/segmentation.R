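#' @include AllClasses.R utils.R
NULL

#' Detect photoreceptor seed positions
#'
#' Automated stand-in for manual cell tracking: local intensity maxima of
#' the Gaussian-smoothed image, kept in decreasing-intensity order subject
#' to a minimum mutual separation, and restricted to pixels brighter than
#' `minIntensity` (default: the Otsu threshold of the smoothed image) so
#' background noise maxima are ignored.
#'
#' @param image a [MosaicImage-class].
#' @param minSeparation minimum seed-to-seed distance, um.
#' @param smoothingSigma Gaussian smoothing SD, um.
#' @param minIntensity optional intensity floor for candidate maxima; NULL
#'   uses the Otsu threshold of the smoothed image.
#' @return A two-column matrix of (x, y) seed positions in um (zero rows on
#'   a structureless image, with a message).
#' @export
detectSeeds <- function(image, minSeparation = 2.0, smoothingSigma = 0.6,
                        minIntensity = NULL) {
  stopifnotScalarPositive(minSeparation, "minSeparation")
  px <- pixelSize(image)
  img <- intensities(image)
  if (diff(range(img)) == 0) {
    message("constant image: no intensity maxima, returning 0 seeds")
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  sm <- if (smoothingSigma > 0)
    asMatrix(EBImage::gblur(EBImage::Image(img), sigma = smoothingSigma / px))
  else img
  if (is.null(minIntensity))
    minIntensity <- EBImage::otsu(EBImage::Image(sm), range = range(sm))
  # candidate maxima: equal to the max over a window of half the separation
  w <- max(1L, as.integer(floor(0.5 * minSeparation / px)))
  brush <- EBImage::makeBrush(2L * w + 1L, shape = "disc")
  dil <- asMatrix(EBImage::dilate(EBImage::Image(sm), brush))
  # the raw intensity must clear the floor as well: FFT-based smoothing
  # wraps bright cells around the field edge and can lift dark border
  # pixels into local maxima
  cand <- which(sm >= dil - 1e-12 & sm > minIntensity & img > minIntensity,
                arr.ind = TRUE)
  if (nrow(cand) == 0) {
    message("no maxima above the intensity floor, returning 0 seeds")
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  ord <- order(sm[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  cx <- pxCentre(cand[, 2], px)
  cy <- pxCentre(cand[, 1], px)
  accX <- numeric(0); accY <- numeric(0)
  minSq <- minSeparation^2
  for (i in seq_along(cx)) {
    if (length(accX) == 0 ||
        min((accX - cx[i])^2 + (accY - cy[i])^2) >= minSq) {
      accX <- c(accX, cx[i]); accY <- c(accY, cy[i])
    }
  }
  cbind(x = accX, y = accY)
}

#' Binarize a mosaic image
#'
#' Applies an intensity contrast threshold: foreground where intensity is
#' at least the threshold. The threshold is chosen by Otsu's method
#' (default), supplied directly (`fixed`), or taken as an intensity
#' percentile.
#'
#' @param image a [MosaicImage-class].
#' @param method "otsu", "fixed" or "percentile".
#' @param parameter the fixed threshold, or the percentile in (0, 100);
#'   ignored for "otsu".
#' @return A [BinaryMask-class] recording the threshold used. An all-false
#'   or all-true mask triggers a warning (degenerate segmentation input).
#' @export
binarize <- function(image, method = c("otsu", "fixed", "percentile"),
                     parameter = NULL) {
  method <- match.arg(method)
  img <- intensities(image)
  thr <- switch(method,
    otsu = {
      if (diff(range(img)) == 0)
        stop("Otsu thresholding is undefined on a constant image",
             call. = FALSE)
      EBImage::otsu(EBImage::Image(img), range = range(img))
    },
    fixed = {
      if (is.null(parameter))
        stop("method 'fixed' needs the threshold in `parameter`",
             call. = FALSE)
      parameter
    },
    percentile = {
      if (is.null(parameter) || parameter <= 0 || parameter >= 100)
        stop("method 'percentile' needs `parameter` in (0, 100)",
             call. = FALSE)
      as.numeric(stats::quantile(img, parameter / 100))
    })
  mask <- img >= thr
  fg <- mean(mask)
  if (fg == 0 || fg == 1)
    warning(sprintf("degenerate mask: foreground fraction %d", as.integer(fg)),
            call. = FALSE)
  new("BinaryMask", mask = mask, thresholdValue = as.numeric(thr),
      method = method)
}

#' Watershed segmentation of photoreceptors
#'
#' Marker-controlled watershed: seeds become markers and regions grow over
#' the smoothed intensity topography (EBImage's `propagate`), restricted to
#' the binary mask. Region assignment is deterministic, so no tie pixels
#' remain and touching cells meet along a shared boundary rather than a
#' background line (a separating line would systematically shave the
#' contact interface off every touching pair; see the methods vignette).
#' When no seeds are given, falls back to a distance-transform watershed
#' of the mask.
#'
#' @param image a [MosaicImage-class].
#' @param mask a [BinaryMask-class] from [binarize()].
#' @param seeds two-column matrix of (x, y) seed positions in um, or NULL
#'   for the distance-transform fallback. Seeds falling on background are
#'   dropped with a warning.
#' @param smoothingSigma smoothing (um) of the intensity topography.
#' @return A [LabelMap-class] with labels 1..K (K = surviving seeds);
#'   every masked pixel belongs to a cell.
#' @export
segmentCells <- function(image, mask, seeds = NULL, smoothingSigma = 0.6) {
  px <- pixelSize(image)
  npx <- pixelsPerSide(image)
  m <- maskMatrix(mask)
  if (!any(m)) {
    message("empty mask: returning an empty LabelMap")
    return(new("LabelMap", labels = matrix(0L, npx, npx), nCells = 0L,
               seedMode = if (is.null(seeds)) "distance" else "provided",
               parameters = list(threshold = thresholdValue(mask))))
  }
  if (is.null(seeds) || nrow(seeds) == 0) {
    dm <- EBImage::distmap(EBImage::Image(m))
    lab <- EBImage::imageData(EBImage::watershed(dm))
    dim(lab) <- c(npx, npx)
    lab <- matrix(as.integer(lab), npx, npx)
    seedMode <- "distance"
  } else {
    ii <- pmin(pmax(as.integer(ceiling(seeds[, 2] / px)), 1L), npx)
    jj <- pmin(pmax(as.integer(ceiling(seeds[, 1] / px)), 1L), npx)
    onMask <- m[cbind(ii, jj)]
    if (any(!onMask)) {
      warning(sum(!onMask), " seed(s) fall on background and were dropped",
              call. = FALSE)
      ii <- ii[onMask]; jj <- jj[onMask]
    }
    if (length(ii) == 0) {
      message("all seeds off-mask: returning an empty LabelMap")
      return(new("LabelMap", labels = matrix(0L, npx, npx), nCells = 0L,
                 seedMode = "provided",
                 parameters = list(threshold = thresholdValue(mask))))
    }
    seedImg <- matrix(0L, npx, npx)
    seedImg[cbind(ii, jj)] <- seq_along(ii)
    topo <- asMatrix(EBImage::gblur(EBImage::Image(intensities(image)),
                                    sigma = max(smoothingSigma, 1e-6) / px))
    lab <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(topo), EBImage::Image(seedImg),
      mask = EBImage::Image(m)))
    dim(lab) <- c(npx, npx)
    lab <- matrix(as.integer(lab), npx, npx)
    seedMode <- attr(seeds, "seedMode") %||% "provided"
  }
  # compact labels to 1..K (dropped seeds leave gaps in the numbering)
  keep <- sort(unique(lab[lab > 0L]))
  if (length(keep) > 0 && (length(keep) < max(keep))) {
    remap <- integer(max(keep)); remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  K <- length(keep)
  new("LabelMap", labels = lab, nCells = as.integer(K), seedMode = seedMode,
      parameters = list(threshold = thresholdValue(mask),
                        smoothingSigma = smoothingSigma))
}

#' Measure segmented cells
#'
#' One record per label: centroid (um, pixel centres, origin at the
#' top-left field corner), transversal area as pixel count times squared
#' pixel pitch, and whether the cell touches the raster border. Border
#' cells are dropped by default so clipped cells do not bias area
#' statistics; keep them (excludeBorder = FALSE) when counting cells for
#' density.
#'
#' @param labelmap a [LabelMap-class].
#' @param geometry the matching [FieldGeometry-class].
#' @param excludeBorder drop border-touching cells (default TRUE).
#' @return data.frame(cellId, x, y, area, touchesBorder); areas in um^2.
#' @export
measureCells <- function(labelmap, geometry, excludeBorder = TRUE) {
  lab <- labelMatrix(labelmap)
  npx <- pixelsPerSide(geometry)
  if (nrow(lab) != npx)
    stop("labelmap raster does not match geometry", call. = FALSE)
  px <- pixelSize(geometry)
  K <- nCells(labelmap)
  if (K == 0L)
    return(data.frame(cellId = integer(), x = numeric(), y = numeric(),
                      area = numeric(), touchesBorder = logical()))
  pos <- which(lab > 0L)
  l <- lab[pos]
  rows <- ((pos - 1L) %% npx) + 1L
  cols <- ((pos - 1L) %/% npx) + 1L
  cnt <- tabulate(l, nbins = K)
  sx <- rowsum(pxCentre(cols, px), l)[, 1]
  sy <- rowsum(pxCentre(rows, px), l)[, 1]
  borderLabs <- unique(c(lab[1, ], lab[npx, ], lab[, 1], lab[, npx]))
  touches <- seq_len(K) %in% borderLabs[borderLabs > 0L]
  out <- data.frame(cellId = seq_len(K), x = sx / cnt, y = sy / cnt,
                    area = cnt * px^2, touchesBorder = touches)
  if (excludeBorder) out <- out[!out$touchesBorder, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment and measure one mosaic image end to end
#'
#' Convenience chain: [detectSeeds()] (unless seeds are supplied),
#' [binarize()], [segmentCells()], [measureCells()] with border cells kept
#' (filter downstream with [areaStats()]).
#'
#' @param image a [MosaicImage-class].
#' @param method,parameter see [binarize()].
#' @param seeds optional seed matrix; NULL triggers automatic detection.
#' @param minSeparation,smoothingSigma see [detectSeeds()].
#' @return list(measurements, labelmap, mask, seeds).
#' @export
segmentMosaic <- function(image, method = "otsu", parameter = NULL,
                          seeds = NULL, minSeparation = 2.0,
                          smoothingSigma = 0.6) {
  auto <- is.null(seeds)
  if (auto)
    seeds <- detectSeeds(image, minSeparation = minSeparation,
                         smoothingSigma = smoothingSigma)
  attr(seeds, "seedMode") <- if (auto) "auto" else "provided"
  mask <- binarize(image, method = method, parameter = parameter)
  lm <- segmentCells(image, mask, seeds = seeds,
                     smoothingSigma = smoothingSigma)
  meas <- measureCells(lm, geometry(image), excludeBorder = FALSE)
  list(measurements = meas, labelmap = lm, mask = mask, seeds = seeds)
}
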