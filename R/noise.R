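#' Modified Thompson Tau critical value
#'
#' The rejection threshold multiplier of the modified Thompson Tau
#' outlier test:
#' \deqn{\tau = \frac{t_{\alpha/2}\,(n-1)}{\sqrt{n}\,\sqrt{n-2+t_{\alpha/2}^2}}}
#' where \eqn{t_{\alpha/2}} is the upper \eqn{\alpha/2} quantile of
#' Student's t distribution with \eqn{n-2} degrees of freedom. A sample
#' point is rejected as an outlier when its absolute deviation from the
#' sample mean exceeds \eqn{\tau S}.
#'
#' @param n sample size, at least 3 (so that df = n - 2 >= 1). Vectorized.
#' @param alpha two-tailed risk, in (0, 1); default 0.001.
#' @return the critical value \eqn{\tau} (positive numeric).
#' @examples
#' modifiedThompsonTau(5, 0.05)   # ~1.571
#' @seealso [detectOutliers()]
#' @export
modifiedThompsonTau <- function(n, alpha = 0.001) {
  if (any(n < 3))
    stop("n must be at least 3 (df = n - 2 >= 1)", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))
}

#' Iterative Thompson Tau outlier rejection
#'
#' At each iteration the sample mean and (n-1)-denominator standard
#' deviation S are computed; only the single most-suspect point (maximal
#' absolute deviation \eqn{\delta_i = |x_i - \bar x|}) is tested against
#' \eqn{\tau S}. If rejected it is removed and the procedure repeats on
#' the reduced sample; it stops when the most-suspect point is retained,
#' when S = 0, or when fewer than 3 points remain. Points tied at the
#' maximal deviation are tested as one group and removed together, which
#' makes the result invariant under permutations of the input.
#'
#' @param values numeric vector of observations (nonempty).
#' @param alpha two-tailed risk passed to [modifiedThompsonTau()].
#' @return list with elements `kept` and `removed` (multisets; `kept`
#'   retains input order of the surviving points).
#' @examples
#' detectOutliers(c(1, 2, 1, 1, 100), alpha = 0.05)
#' @export
detectOutliers <- function(values, alpha = 0.001) {
  if (!length(values)) stop("values must be nonempty", call. = FALSE)
  kept <- values
  removed <- values[0]
  repeat {
    n <- length(kept)
    if (n < 3L) break
    s <- stats::sd(kept)
    if (s == 0) break
    d <- abs(kept - mean(kept))
    dmax <- max(d)
    if (dmax > modifiedThompsonTau(n, alpha) * s) {
      hit <- d == dmax
      removed <- c(removed, kept[hit])
      kept <- kept[!hit]
    } else break
  }
  list(kept = kept, removed = removed)
}

#' Local background-noise estimation around a candidate position
#'
#' Takes the per-position total alternative-read counts of the profile
#' over a window of `windowBp` base pairs centered on `centerPos` (clipped
#' at the region edges), removes the center position's own contribution
#' (unless `includeCenter`), strips zeros, applies [detectOutliers()], and
#' reports the largest surviving count as the local background noise. The
#' noise rate divides that count by the mean declared depth over the
#' window. With fewer than 3 nonzero counts the outlier test is skipped
#' and the raw maximum is used (0 for an empty sample).
#'
#' @param profile a [RegionProfile-class].
#' @param centerPos 1-based genomic position inside the profile's region.
#' @param windowBp total window span in bp (200 means +/-100 around the
#'   center).
#' @param alpha two-tailed risk of the outlier test.
#' @param includeCenter keep the center position's alternative count in
#'   the noise sample.
#' @return a [NoiseEstimate-class].
#' @examples
#' prof <- simulateProfiles(simulationConfig(
#'   regions = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200)),
#'   depth = 500, errorRate = 0.002, seed = 7))$profiles[[1]]
#' localBackgroundNoise(prof, 100)
#' @export
localBackgroundNoise <- function(profile, centerPos, windowBp = 200,
                                 alpha = 0.001, includeCenter = FALSE) {
  if (centerPos < GenomicRanges::start(profile@region) ||
      centerPos > GenomicRanges::end(profile@region))
    stop("centerPos outside the profile's region", call. = FALSE)
  half <- floor(windowBp / 2)
  lo <- max(centerPos - half, GenomicRanges::start(profile@region))
  hi <- min(centerPos + half, GenomicRanges::end(profile@region))
  sel <- profile@pos >= lo & profile@pos <= hi
  if (!any(sel))
    stop(sprintf("window %d-%d contains no covered positions", lo, hi),
         call. = FALSE)
  ac <- altCounts(profile)[sel]
  dp <- profile@depth[sel]
  if (!includeCenter)
    ac <- ac[profile@pos[sel] != centerPos]
  sample <- ac[ac > 0L]
  if (length(sample) == 0L) {
    kept <- integer(0); removed <- integer(0); nc <- 0L
  } else if (length(sample) < 3L) {
    kept <- sample; removed <- integer(0); nc <- max(sample)
  } else {
    tr <- detectOutliers(sample, alpha)
    kept <- tr$kept; removed <- tr$removed
    nc <- max(kept)
  }
  meanDepth <- mean(dp)
  rate <- if (meanDepth > 0) min(nc / meanDepth, 1) else 0
  new("NoiseEstimate", noiseCount = as.integer(nc), noiseRate = rate,
      kept = as.integer(kept), removed = as.integer(removed),
      windowStart = as.integer(lo), windowEnd = as.integer(hi),
      meanDepth = meanDepth)
}
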