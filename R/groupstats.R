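#' @include AllClasses.R utils.R
NULL

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal distribution with mean and SD
#' estimated from the sample itself (the Lilliefors correction — the plain
#' KS null distribution would be anti-conservative here). Uses the
#' analytic approximation of `nortest::lillie.test` for n >= 5 and a
#' seeded Monte-Carlo null (B = 2000) for n of 3 or 4, below that
#' function's minimum.
#'
#' @param x numeric sample, n >= 3, non-constant.
#' @return the p-value.
#' @export
normalityCheck <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("normality check needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant sample: normality check is degenerate", call. = FALSE)
  if (length(x) >= 5) return(nortest::lillie.test(x)$p.value)
  d0 <- lillieStat(x)
  n <- length(x)
  withSeed(deriveSeed(20240811, "lilliefors-mc", n), {
    dnull <- replicate(2000, lillieStat(stats::rnorm(n)))
    mean(dnull >= d0)
  })
}

# Lilliefors statistic: sup-distance between the ECDF and the normal CDF
# with sample-estimated parameters
lillieStat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

#' Two-group comparison with the study's decision rule
#'
#' Applies the published statistical procedure verbatim: both samples are
#' checked for normality with the (Lilliefors-corrected) Kolmogorov-
#' Smirnov test at alpha = 0.05; when both pass, Student's t-test is used
#' (paired when requested), otherwise the Mann-Whitney U test. All tests
#' are two-sided; significance is declared at p < 0.05.
#'
#' @param a,b numeric samples, each n >= 3 (equal length when paired).
#' @param paired logical; paired Student's t on the t branch.
#' @param alpha normality-gate level (0.05).
#' @return A [ComparisonResult-class].
#' @examples
#' set.seed(1)
#' compareGroups(rnorm(16, 10.04, 0.42), rnorm(16, 14.82, 1.49))
#' @export
compareGroups <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    stop("both samples need n >= 3", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison needs equal sample sizes", call. = FALSE)
  pa <- normalityCheck(a)
  pb <- normalityCheck(b)
  if (pa > alpha && pb > alpha) {
    if (identical(a, b)) {
      # degenerate identity: zero effect by construction
      stat <- 0; pv <- 1
    } else {
      tt <- stats::t.test(a, b, paired = paired)
      stat <- unname(tt$statistic); pv <- tt$p.value
    }
    used <- if (paired) "paired_t" else "student_t"
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    stat <- unname(wt$statistic); pv <- wt$p.value
    used <- "mann_whitney_u"
  }
  new("ComparisonResult", testUsed = used, statistic = stat, pValue = pv,
      normalityP = c(pa, pb), n = c(length(a), length(b)),
      significant = pv < 0.05, paired = paired)
}

#' Contrast eccentricity locations on a per-image metric
#'
#' Pools per-image metric values into the two cells of a partition of the
#' four locations (e.g. {1, 4} vs {2, 3}) and compares them with the
#' study's decision rule (unpaired).
#'
#' @param metrics data.frame of per-image rows from [mosaicMetrics()].
#' @param partition list of two integer vectors partitioning 1:4.
#' @param value metric column to contrast.
#' @return A [ComparisonResult-class].
#' @export
locationContrast <- function(metrics, partition = list(c(1, 4), c(2, 3)),
                             value = "inflamedCountFraction") {
  if (length(partition) != 2 || length(partition[[1]]) == 0 ||
      length(partition[[2]]) == 0)
    stop("partition must be two non-empty sets of locations", call. = FALSE)
  if (length(intersect(partition[[1]], partition[[2]])) > 0)
    stop("partition cells overlap", call. = FALSE)
  if (!value %in% names(metrics))
    stop("metric column '", value, "' not found", call. = FALSE)
  va <- metrics[[value]][metrics$locationIndex %in% partition[[1]]]
  vb <- metrics[[value]][metrics$locationIndex %in% partition[[2]]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0)
    stop("a partition cell selected no images", call. = FALSE)
  compareGroups(va, vb, paired = FALSE)
}
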