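#' @rdname RegionProfile-class
#' @param x a `RegionProfile` (or `NoiseEstimate` for its accessors).
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' @rdname RegionProfile-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname RegionProfile-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname RegionProfile-class
#' @export
setGeneric("refBases", function(x) standardGeneric("refBases"))

#' @rdname RegionProfile-class
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname RegionProfile-class
#' @export
setGeneric("altObservations", function(x) standardGeneric("altObservations"))

#' Per-position total alternative-read counts
#'
#' The noise sample of the method: at each position of the profile, the
#' sum of read counts over all alternative alleles (substitutions and
#' indels pooled).
#'
#' @param x a [RegionProfile-class].
#' @return integer vector, parallel to `positions(x)`.
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname NoiseEstimate-class
#' @param x a `NoiseEstimate`.
#' @export
setGeneric("noiseCount", function(x) standardGeneric("noiseCount"))

#' @rdname NoiseEstimate-class
#' @export
setGeneric("noiseRate", function(x) standardGeneric("noiseRate"))

#' @describeIn RegionProfile-class target region as a `GRanges`.
#' @export
setMethod("region", "RegionProfile", function(x) x@region)

#' @describeIn RegionProfile-class 1-based genomic positions with data.
#' @export
setMethod("positions", "RegionProfile", function(x) x@pos)

#' @describeIn RegionProfile-class declared depth per position.
#' @export
setMethod("depths", "RegionProfile", function(x) x@depth)

#' @describeIn RegionProfile-class reference base per position.
#' @export
setMethod("refBases", "RegionProfile", function(x) x@refBase)

#' @describeIn RegionProfile-class reference-supporting reads per position.
#' @export
setMethod("refCounts", "RegionProfile", function(x) x@refCount)

#' @describeIn RegionProfile-class per-position list of alternative-allele
#'   observations (`allele`, `count`, `fwd`, `rev`, `quals`).
#' @export
setMethod("altObservations", "RegionProfile", function(x) x@alts)

#' @rdname altCounts
#' @export
setMethod("altCounts", "RegionProfile", function(x) {
  vapply(x@alts, function(a) {
    if (!length(a)) 0L else sum(vapply(a, `[[`, integer(1), "count"))
  }, integer(1))
})

#' @describeIn NoiseEstimate-class background-noise read count.
#' @export
setMethod("noiseCount", "NoiseEstimate", function(x) x@noiseCount)

#' @describeIn NoiseEstimate-class background-noise rate
#'   (count / mean window depth).
#' @export
setMethod("noiseRate", "NoiseEstimate", function(x) x@noiseRate)

setMethod("show", "RegionProfile", function(object) {
  r <- object@region
  cat(sprintf("RegionProfile: %s:%d-%d (%d positions)\n",
              as.character(GenomicRanges::seqnames(r)),
              GenomicRanges::start(r), GenomicRanges::end(r),
              length(object@pos)))
  if (length(object@pos)) {
    ac <- altCounts(object)
    cat(sprintf("  mean depth %.1f | positions with alt reads: %d | max alt count: %d\n",
                mean(object@depth), sum(ac > 0L), max(ac)))
  }
  invisible(NULL)
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf(
    "NoiseEstimate: count %d (rate %.3g) over window %d-%d (mean depth %.1f)\n",
    object@noiseCount, object@noiseRate, object@windowStart,
    object@windowEnd, object@meanDepth))
  cat(sprintf("  sample kept n=%d, removed as outliers n=%d\n",
              length(object@kept), length(object@removed)))
  invisible(NULL)
})

setMethod("show", "CallerConfig", function(object) {
  cat("CallerConfig:\n")
  p <- configAsList(object)
  for (k in names(p)) cat(sprintf("  %s = %s\n", k, format(p[[k]])))
  invisible(NULL)
})

## flat named list of effective parameters, used for VCF header echo
configAsList <- function(config) {
  list(alpha = config@alpha, window_bp = config@windowBp,
       noise_multiplier = config@noiseMultiplier,
       min_mean_phred = config@minMeanPhred,
       max_phred_sd = config@maxPhredSd,
       strand_balance_low = config@strandBalanceLow,
       strand_balance_high = config@strandBalanceHigh,
       vaf_min_snv = config@vafMinSnv, vaf_min_indel = config@vafMinIndel,
       include_center = config@includeCenter, pass_only = config@passOnly)
}
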