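#' @include AllClasses.R AllGenerics.R
NULL

#' 2D Fourier power spectrum of a mosaic image
#'
#' Squared modulus of the DFT of the mean-subtracted image, optionally
#' Hann-windowed (recommended: it suppresses edge leakage that otherwise
#' smears the ring), with the zero frequency moved to the centre.
#'
#' @param image a [MosaicImage-class] or a square numeric matrix.
#' @param window "hann" or "none".
#' @return Square matrix of power values, DC at (n/2 + 1, n/2 + 1).
#' @export
powerSpectrum <- function(image, window = c("hann", "none")) {
  window <- match.arg(window)
  m <- if (is(image, "MosaicImage")) intensities(image) else image
  if (nrow(m) != ncol(m)) stop("image must be square", call. = FALSE)
  n <- nrow(m)
  m <- m - mean(m)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    m <- m * outer(w, w)
  }
  p <- Mod(stats::fft(m))^2
  h <- n %/% 2
  sh <- c((h + 1):n, 1:h)
  p[sh, sh]
}

#' Radially averaged power spectrum
#'
#' Averages a centred 2D power grid in annular bins one frequency sample
#' (1/sideLength cycles/um) wide, giving the 1D profile in which the
#' Yellott ring of a quasi-regular mosaic appears as a peak.
#'
#' @param power centred power grid from [powerSpectrum()].
#' @param pixelSizeUm pixel pitch in um.
#' @param window bookkeeping tag stored on the result.
#' @return A [RadialSpectrum-class]; `dcExcludedRadius` is set to two field
#'   periods (2 / sideLength).
#' @export
radialProfile <- function(power, pixelSizeUm, window = "hann") {
  stopifnotScalarPositive(pixelSizeUm, "pixelSizeUm")
  n <- nrow(power)
  h <- n %/% 2
  df <- 1 / (n * pixelSizeUm)
  f1 <- (seq_len(n) - 1 - h) * df
  rad <- sqrt(outer(f1^2, f1^2, "+"))
  bin <- as.integer(floor(rad / df + 0.5))
  nyq <- 1 / (2 * pixelSizeUm)
  keep <- bin <= h                       # drop corner bins beyond Nyquist
  prof <- rowsum(as.vector(power)[keep], bin[keep])
  cnts <- rowsum(rep(1L, sum(keep)), bin[keep])
  bins <- as.integer(rownames(prof))
  ord <- order(bins)
  new("RadialSpectrum",
      frequencies = bins[ord] * df,
      power = (prof[ord, 1] / cnts[ord, 1]),
      counts = as.integer(cnts[ord, 1]),
      window = window,
      dcExcludedRadius = min(2 * df, nyq / 2))
}

#' Estimate the inter-cell spacing from the Yellott ring
#'
#' Finds the ring peak in the radially averaged spectrum: the profile is
#' smoothed with a pixel-count-weighted 3-bin moving average, the maximum
#' inside the search band is refined by 3-point parabolic interpolation,
#' and the spacing follows from the first reciprocal-lattice ring of a
#' triangular mosaic, D_PR = 2 / (sqrt(3) f_ring). The alternative
#' row-spacing-free convention D_PR = 1 / f_ring is available but is
#' inconsistent with the lattice-recovery oracle (see the vignette).
#'
#' Quality is the smoothed peak power over the pixel-weighted mean power of
#' the off-peak band; estimates below `minQuality` are flagged unreliable.
#'
#' @param profile a [RadialSpectrum-class].
#' @param searchBand numeric(2), cycles/um; default from the profile's DC
#'   exclusion radius up to Nyquist. Bins averaging fewer than
#'   `minSupport` spectrum pixels are skipped (their means are too noisy
#'   to rank) unless an explicit band retains nothing else.
#' @param minQuality reliability gate on the peak/background ratio.
#' @param minSupport minimum pixels per usable bin.
#' @param conversion "hex-row" (default) or "reciprocal" for D = 1/f.
#' @return A [SpacingEstimate-class].
#' @export
estimateSpacing <- function(profile, searchBand = NULL, minQuality = 2,
                            minSupport = 30L,
                            conversion = c("hex-row", "reciprocal")) {
  conversion <- match.arg(conversion)
  f <- profile@frequencies
  p <- profile@power
  cn <- as.numeric(profile@counts)
  nyq <- max(f)
  if (is.null(searchBand)) searchBand <- c(profile@dcExcludedRadius, nyq)
  # count-weighted 3-bin moving average
  num <- stats::filter(p * cn, rep(1, 3))
  den <- stats::filter(cn, rep(1, 3))
  sm <- as.numeric(num / den)
  idx <- which(f > searchBand[1] & f < searchBand[2] & !is.na(sm) &
               cn >= minSupport)
  if (length(idx) < 3)
    idx <- which(f > searchBand[1] & f < searchBand[2] & !is.na(sm))
  if (length(idx) < 3)
    stop("search band contains fewer than 3 usable frequency bins",
         call. = FALSE)
  pk <- idx[which.max(sm[idx])]
  df <- f[2] - f[1]
  # 3-point parabolic refinement around the peak bin
  delta <- 0
  if (pk > 1 && pk < length(sm) && !is.na(sm[pk - 1]) && !is.na(sm[pk + 1])) {
    y1 <- sm[pk - 1]; y2 <- sm[pk]; y3 <- sm[pk + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) delta <- max(-0.5, min(0.5, 0.5 * (y1 - y3) / denom))
  }
  fring <- f[pk] + delta * df
  off <- idx[abs(idx - pk) > 3]
  bg <- if (length(off) > 0) sum(p[off] * cn[off]) / sum(cn[off]) else NA_real_
  quality <- if (is.na(bg) || bg <= 0) Inf else sm[pk] / bg
  d <- if (conversion == "hex-row") 2 / (sqrt(3) * fring) else 1 / fring
  new("SpacingEstimate", dPR = d, ringFrequency = fring,
      quality = quality, reliable = is.finite(quality) &&
        quality >= minQuality)
}

#' Estimate mosaic spacing directly from an image
#'
#' Chains [powerSpectrum()], [radialProfile()] and [estimateSpacing()].
#'
#' @param image a [MosaicImage-class].
#' @param window see [powerSpectrum()].
#' @param ... passed to [estimateSpacing()].
#' @return A [SpacingEstimate-class].
#' @export
mosaicSpacing <- function(image, window = "hann", ...) {
  p <- powerSpectrum(image, window = window)
  prof <- radialProfile(p, pixelSize(image), window = window)
  estimateSpacing(prof, ...)
}

#' @describeIn computeMarp evaluate the resolving-power formula
#'   MARP = PND / (57.3 * D_PR * sqrt(3)) with D_PR converted to mm.
setMethod("computeMarp", "SpacingEstimate", function(spacing, eye) {
  res <- computeMarp(spacing@dPR, eye)
  res@spacing <- spacing
  res
})

#' @describeIn computeMarp numeric spacing in micrometres.
setMethod("computeMarp", "numeric", function(spacing, eye) {
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number (um)", call. = FALSE)
  dmm <- spacing * 1e-3
  val <- eye@posteriorNodalDistance /
    (eye@degreesPerRadian * dmm * eye@hexNyquistFactor)
  new("MarpResult", marp = val,
      spacing = new("SpacingEstimate", dPR = spacing,
                    ringFrequency = 2 / (sqrt(3) * spacing),
                    quality = Inf, reliable = TRUE),
      eye = eye)
})
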