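#' @include AllClasses.R utils.R
NULL

#' Nominal spacing of a hexagonally packed mosaic at a given density
#'
#' For a triangular (hexagonal-packing) lattice, each cell occupies
#' sqrt(3)/2 * D^2, so the nearest-neighbour spacing at planar density
#' \eqn{\rho} is \eqn{D = \sqrt{2 / (\sqrt{3}\rho)}}.
#'
#' @param density cells per mm^2.
#' @return spacing in micrometres.
#' @examples
#' hexSpacing(43951)  # ~5.126 um
#' @export
hexSpacing <- function(density) {
  stopifnotScalarPositive(density, "density")
  sqrt(2 / (sqrt(3) * density * 1e-6))
}

#' Generate jittered hexagonal cell centres
#'
#' Lays a triangular lattice at the nearest-neighbour spacing implied by
#' `density` (see [hexSpacing()]) over the field, with a random lattice
#' phase, displaces every node by isotropic Gaussian jitter of SD
#' `jitter * D`, and keeps the nodes that land inside the field.
#'
#' @param density target planar density, cells per mm^2.
#' @param geometry a [FieldGeometry-class].
#' @param jitter displacement SD as a proportion of the nominal spacing,
#'   in [0, 0.5).
#' @param seed integer RNG seed; the result is a pure function of
#'   (arguments, seed).
#' @return A two-column matrix of (x, y) positions in micrometres.
#' @examples
#' pts <- generateHexCenters(43951, FieldGeometry(), jitter = 0, seed = 1)
#' nrow(pts)  # ~356 for a 90 x 90 um field
#' @export
generateHexCenters <- function(density, geometry = FieldGeometry(),
                               jitter = 0.12, seed = 1) {
  stopifnotScalarPositive(density, "density")
  if (jitter < 0 || jitter >= 0.5)
    stop("jitter must lie in [0, 0.5)", call. = FALSE)
  side <- sideLength(geometry)
  expected <- density * 1e-6 * side^2
  if (expected < 9)
    stop(sprintf(
      "field too small: %.6g x %.6g um holds only %.1f cells at %.6g /mm^2",
      side, side, expected, density), call. = FALSE)
  D <- hexSpacing(density)
  rowSpacing <- D * sqrt(3) / 2
  withSeed(seed, {
    ox <- stats::runif(1, 0, D)
    oy <- stats::runif(1, 0, rowSpacing)
    ys <- seq(-D, side + D, by = rowSpacing) + oy
    pts <- do.call(rbind, lapply(seq_along(ys), function(k) {
      xs <- seq(-D, side + D, by = D) + ox + (k %% 2) * D / 2
      cbind(xs, ys[k])
    }))
    if (jitter > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter * D), ncol = 2)
    keep <- pts[, 1] >= 0 & pts[, 1] <= side &
            pts[, 2] >= 0 & pts[, 2] <= side
    pts <- pts[keep, , drop = FALSE]
    colnames(pts) <- c("x", "y")
    pts
  })
}

#' Assign per-cell transversal areas and inflammation flags
#'
#' Implements the generator's two-component lognormal area model. A
#' sample-level mean is drawn once from Normal(meanArea, betweenSampleSD);
#' each cell is flagged inflamed with probability `inflamedFraction` and its
#' lognormal component mean is `inflamedAreaRatio` times the healthy
#' component mean, the two rescaled so the expected mosaic mean equals the
#' drawn sample-level mean. Per-cell coefficient of variation is
#' `withinAreaCV` in both components.
#'
#' @param centers two-column matrix of (x, y) positions, um.
#' @param profile a [GroupProfile-class].
#' @param seed integer RNG seed.
#' @return data.frame(cellId, x, y, trueArea, inflamed) with attribute
#'   `"sampleMean"` holding the drawn sample-level mean (um^2).
#' @export
assignAreas <- function(centers, profile, seed = 1) {
  validObject(profile)
  if (is.null(dim(centers)) || nrow(centers) == 0)
    stop("centers must be a non-empty two-column matrix", call. = FALSE)
  withSeed(seed, {
    m <- stats::rnorm(1, profile@meanArea, profile@betweenSampleSD)
    if (m <= 0)
      stop("drawn sample-level mean area is non-positive; ",
           "profile parameters imply non-positive areas", call. = FALSE)
    n <- nrow(centers)
    f <- profile@inflamedFraction
    r <- profile@inflamedAreaRatio
    inflamed <- stats::runif(n) < f
    healthyMean <- m / (1 - f + f * r)
    mu <- ifelse(inflamed, r * healthyMean, healthyMean)
    s2 <- log(1 + profile@withinAreaCV^2)
    areas <- stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    out <- data.frame(cellId = seq_len(n), x = centers[, 1], y = centers[, 2],
                      trueArea = areas, inflamed = inflamed)
    attr(out, "sampleMean") <- m
    out
  })
}

#' Render a cell table to a TPEF-like intensity image
#'
#' Each cell becomes a bright blob whose support area equals its true
#' transversal area: a hard disk of radius sqrt(area/pi) by default, or an
#' isotropic Gaussian whose full-width-half-maximum disk has that area.
#' Overlapping blobs combine by maximum (saturating autofluorescence
#' brightness), a dark interstitial background is added, optional global
#' edge softening is applied, then Poisson and/or Gaussian noise.
#'
#' @param cells data.frame from [assignAreas()] (needs x, y, trueArea;
#'   cellId/inflamed carried into the ground truth when present).
#' @param geometry a [FieldGeometry-class].
#' @param blob list(shape = "disk" or "gaussian", edgeSoftness = um of
#'   Gaussian softening applied to the noise-free rendering; 0 = hard).
#' @param noise list(background = baseline intensity in [0, 1),
#'   gaussianSD = additive Gaussian noise SD, poisson = logical,
#'   poissonScale = photons at unit intensity when poisson is TRUE).
#' @param scheme,group metadata carried on the image.
#' @param seed integer RNG seed (noise only; the blob raster is
#'   deterministic).
#' @return A [MosaicImage-class] carrying `cells` as ground truth.
#' @export
renderMosaic <- function(cells, geometry = FieldGeometry(),
                         blob = list(shape = "disk", edgeSoftness = 0),
                         noise = list(background = 0.08, gaussianSD = 0.02,
                                      poisson = FALSE, poissonScale = 100),
                         scheme = SamplingScheme(), group = "unknown",
                         seed = 1) {
  shape <- match.arg(blob$shape %||% "disk", c("disk", "gaussian"))
  edgeSoft <- blob$edgeSoftness %||% 0
  bg <- noise$background %||% 0.08
  gsd <- noise$gaussianSD %||% 0.02
  usePoisson <- isTRUE(noise$poisson)
  pScale <- noise$poissonScale %||% 100
  npx <- pixelsPerSide(geometry)
  px <- pixelSize(geometry)
  side <- sideLength(geometry)
  img <- matrix(0, npx, npx)      # [row = y, col = x]
  painted <- matrix(0L, npx, npx)
  n <- if (is.null(cells) || nrow(cells) == 0) 0L else nrow(cells)
  for (i in seq_len(n)) {
    x <- cells$x[i]; y <- cells$y[i]
    if (x < 0 || x > side || y < 0 || y > side)
      stop("cell ", i, " lies outside the field", call. = FALSE)
    ri <- sqrt(cells$trueArea[i] / pi)
    # rasterisation support: disk radius, or 2.5 sigma for gaussian blobs
    sig <- ri / sqrt(2 * log(2))
    rs <- if (shape == "disk") ri else 2.5 * sig
    j0 <- max(1L, floor((x - rs) / px)); j1 <- min(npx, ceiling((x + rs) / px) + 1)
    i0 <- max(1L, floor((y - rs) / px)); i1 <- min(npx, ceiling((y + rs) / px) + 1)
    jj <- j0:j1; ii <- i0:i1
    dd <- outer((pxCentre(ii, px) - y)^2, (pxCentre(jj, px) - x)^2, "+")
    if (shape == "disk") {
      sel <- dd <= ri^2
      img[ii, jj][sel] <- pmax(img[ii, jj][sel], 1)
      painted[ii, jj][sel] <- painted[ii, jj][sel] + 1L
    } else {
      val <- exp(-dd / (2 * sig^2))
      img[ii, jj] <- pmax(img[ii, jj], val)
      sel <- val >= 0.5
      painted[ii, jj][sel] <- painted[ii, jj][sel] + 1L
    }
  }
  totalPainted <- sum(painted > 0L)
  overlapped <- sum(painted > 1L)
  if (totalPainted > 0 && overlapped / totalPainted > 0.05)
    warning(sprintf(
      "%.1f%% of blob area overlaps; watershed ground truth degrades",
      100 * overlapped / totalPainted), call. = FALSE)
  img <- bg + img * (1 - bg)
  if (edgeSoft > 0)
    img <- asMatrix(EBImage::gblur(EBImage::Image(img), sigma = edgeSoft / px))
  withSeed(seed, {
    if (usePoisson)
      img <- matrix(stats::rpois(npx * npx, img * pScale) / pScale, npx, npx)
    if (gsd > 0)
      img <- img + matrix(stats::rnorm(npx * npx, 0, gsd), npx, npx)
  })
  img[img < 0] <- 0
  gt <- if (n > 0) {
    data.frame(cellId = cells$cellId %||% seq_len(n), x = cells$x,
               y = cells$y, trueArea = cells$trueArea,
               inflamed = cells$inflamed %||% rep(FALSE, n))
  } else emptyGroundTruth()
  MosaicImage(img, geometry = geometry, scheme = scheme, group = group,
              groundTruth = gt, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

asMatrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Generate one synthetic mosaic image for a group profile
#'
#' Convenience wrapper: centres via [generateHexCenters()], areas via
#' [assignAreas()], rendering via [renderMosaic()], with sub-seeds derived
#' from `seed` so the image is a pure function of (arguments, seed).
#'
#' @param profile a [GroupProfile-class].
#' @param geometry a [FieldGeometry-class].
#' @param scheme a [SamplingScheme-class].
#' @param blob,noise see [renderMosaic()].
#' @param seed integer RNG seed.
#' @return A [MosaicImage-class].
#' @export
simulateMosaic <- function(profile, geometry = FieldGeometry(),
                           scheme = SamplingScheme(), blob = NULL,
                           noise = NULL, seed = 1) {
  blob <- blob %||% list(shape = "disk", edgeSoftness = 0)
  noise <- noise %||% list(background = 0.08, gaussianSD = 0.02,
                           poisson = FALSE, poissonScale = 100)
  pts <- generateHexCenters(profile@targetDensity, geometry,
                            jitter = profile@latticeJitter,
                            seed = deriveSeed(seed, "centers"))
  cells <- assignAreas(pts, profile, seed = deriveSeed(seed, "areas"))
  img <- renderMosaic(cells, geometry, blob = blob, noise = noise,
                      scheme = scheme, group = profile@group,
                      seed = deriveSeed(seed, "noise"))
  img@seed <- as.integer(seed %% .Machine$integer.max)
  img
}

#' Generate a full synthetic study
#'
#' Emulates the study layout: for each group, `nPerGroup` retinas, each
#' imaged in the four quadrants (ST, SN, IT, IN) at the four eccentricity
#' locations, i.e. `nPerGroup * 16` images per group. Per-location profile
#' overrides are supported; by default every location uses the group's
#' global profile (per-location means are deliberately not hard-coded).
#'
#' @param nPerGroup retinas per group (study default 4).
#' @param profiles named list of [GroupProfile-class] objects, one per
#'   group to simulate; each element may instead be a list of four profiles
#'   indexed by location.
#' @param geometry a [FieldGeometry-class].
#' @param blob,noise see [renderMosaic()].
#' @param seed master seed; per-image seeds are derived with
#'   [deriveSeed()] from (seed, group, quadrant, location, replicate).
#' @return A list of [MosaicImage-class] objects named
#'   `<group>_r<replicate>_<quadrant>_<location>`.
#' @examples
#' study <- generateStudy(nPerGroup = 1,
#'   profiles = list(control = controlProfile()),
#'   geometry = FieldGeometry(30, 128L), seed = 1)
#' length(study)  # 16
#' @export
generateStudy <- function(nPerGroup = 4,
                          profiles = list(control = controlProfile(),
                                          diabetic = diabeticProfile()),
                          geometry = FieldGeometry(), blob = NULL,
                          noise = NULL, seed = 1) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list (names = group labels)",
         call. = FALSE)
  quadrants <- c("ST", "SN", "IT", "IN")
  out <- list()
  for (grp in names(profiles)) {
    prof <- profiles[[grp]]
    perLocation <- is.list(prof) && !is(prof, "GroupProfile")
    if (perLocation && length(prof) != 4)
      stop("per-location profiles for group '", grp,
           "' must have exactly 4 elements", call. = FALSE)
    for (rep_ in seq_len(nPerGroup)) {
      for (q in quadrants) {
        for (loc in 1:4) {
          p <- if (perLocation) prof[[loc]] else prof
          if (!is(p, "GroupProfile"))
            stop("missing GroupProfile for group '", grp, "' location ",
                 loc, call. = FALSE)
          sch <- SamplingScheme(quadrant = q, locationIndex = loc)
          s <- deriveSeed(seed, grp, q, loc, rep_)
          img <- simulateMosaic(p, geometry, scheme = sch, blob = blob,
                                noise = noise, seed = s)
          img@group <- p@group
          nm <- sprintf("%s_r%d_%s_%d", grp, rep_, q, loc)
          out[[nm]] <- img
        }
      }
    }
  }
  out
}
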