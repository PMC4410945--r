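#' Paired t-test between per-subject estimates
#'
#' One-sample t-test on the paired differences with a two-sided p-value.
#' Pairs with missing values (e.g. subjects flagged invalid) are dropped
#' pairwise. Zero-variance differences are handled by convention: p = 1 when
#' the common difference is zero, p = 0 otherwise, with a message.
#'
#' @param a,b numeric vectors of per-subject values, paired by position.
#' @return list with `t`, `p`, `meanDiff`, `n`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 3) stop("need at least 3 complete pairs")
  if (sd(d) == 0) {
    message("zero-variance paired differences; p by sign convention")
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p = if (mean(d) == 0) 1 else 0,
                meanDiff = mean(d), n = length(d)))
  }
  tt <- t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, meanDiff = mean(d),
       n = length(d))
}

#' Bland-Altman agreement between two measurement sets
#'
#' Mean paired difference and 95% limits of agreement
#' (mean +/- 1.96 x sample SD of the differences).
#'
#' @param a,b numeric vectors, paired by position.
#' @return list with `meanDiff`, `lower`, `upper`, `n`.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  m <- mean(d); s <- sd(d)
  list(meanDiff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       n = length(d))
}

#' Resting ASL signal-to-noise ratio
#'
#' Mean of a single tag-control difference volume over the ROI (before any
#' noisy-voxel exclusion) divided by the standard deviation of the same
#' volume over a non-brain noise region.
#'
#' @param differenceVolume numeric vector, one value per voxel (control minus
#'   tag at baseline).
#' @param roi integer voxel indices of the signal ROI.
#' @param noiseRegion integer voxel indices of the non-brain region
#'   (>= 30 voxels, disjoint from the ROI).
#' @return numeric SNR.
#' @export
aslSNR <- function(differenceVolume, roi, noiseRegion) {
  if (length(noiseRegion) < 30)
    stop("noise region must contain at least 30 voxels")
  if (length(intersect(roi, noiseRegion)))
    stop("noise region must be disjoint from the ROI")
  s <- sd(differenceVolume[noiseRegion])
  if (!is.finite(s) || s == 0) stop("noise region has zero variance")
  mean(differenceVolume[roi]) / s
}
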