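#' RegionProfile: per-position pileup observations for one target region
#'
#' Holds the decoded pileup columns of a single target region: position,
#' reference base, total depth, reference-supporting read count and
#' qualities, and the alternative-allele observations (count, strand split,
#' base qualities per allele). The per-position total alternative-read
#' count (`altCounts`) is the sample from which local background noise is
#' estimated.
#'
#' Alternative alleles are keyed `"A"/"C"/"G"/"T"` for substitutions,
#' `"+SEQ"` for an insertion of SEQ after the position, and `"-SEQ"` for a
#' deletion of the following reference bases SEQ. Indel-supporting reads
#' report the anchor reference base as well (mpileup semantics), so
#' `refCount` includes them at the anchor; their allele quality is the
#' anchor-base quality.
#'
#' @slot region `GRanges` of length 1: the target region (1-based
#'   inclusive).
#' @slot pos integer vector, strictly increasing 1-based positions.
#' @slot refBase character vector of reference bases (A/C/G/T/N).
#' @slot depth integer vector, declared pileup depth per position.
#' @slot refCount integer vector, reference-supporting reads per position.
#' @slot refQuals list of integer vectors: Phred qualities of
#'   reference-supporting reads (indel-carrier anchors first).
#' @slot starCount integer vector: deleted-base placeholders (`*`) plus
#'   ambiguous (N) base calls per position; they consume depth but belong
#'   to no allele.
#' @slot alts list (one element per position) of per-allele observation
#'   lists with fields `allele`, `count`, `fwd`, `rev`, `quals`.
#'
#' @seealso [parsePileup()], [altCounts()], [simulatePileup()]
#' @export
setClass("RegionProfile",
  slots = c(
    region    = "GRanges",
    pos       = "integer",
    refBase   = "character",
    depth     = "integer",
    refCount  = "integer",
    refQuals  = "list",
    starCount = "integer",
    alts      = "list"
  )
)

setValidity("RegionProfile", function(object) {
  n <- length(object@pos)
  msg <- character(0)
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single range")
  for (s in c("refBase", "depth", "refCount", "refQuals", "starCount", "alts"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' length differs from pos", s))
  if (n > 1L && any(diff(object@pos) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (n > 0L) {
    if (any(object@pos < GenomicRanges::start(object@region)) ||
        any(object@pos > GenomicRanges::end(object@region)))
      msg <- c(msg, "positions outside the region bounds")
    ## substitutions + '*' placeholders never exceed declared depth;
    ## indel events ride on anchor reads and consume no depth slot
    subCounts <- vapply(object@alts, function(a) {
      if (!length(a)) return(0L)
      sum(vapply(a, function(x)
        if (substr(x$allele, 1L, 1L) %in% c("+", "-")) 0L else x$count,
        integer(1)))
    }, integer(1))
    if (any(object@refCount + subCounts + object@starCount > object@depth))
      msg <- c(msg, "ref + substitution + placeholder counts exceed depth")
    badObs <- vapply(object@alts, function(a) {
      any(vapply(a, function(x)
        x$fwd + x$rev != x$count || length(x$quals) != x$count, logical(1)))
    }, logical(1))
    if (any(badObs))
      msg <- c(msg, "allele observation with inconsistent strand/quality counts")
  }
  if (length(msg)) msg else TRUE
})

#' NoiseEstimate: result of local background-noise estimation
#'
#' Produced by [localBackgroundNoise()]. The noise count is the largest
#' per-position alternative-read count in the window that survived
#' iterative modified Thompson Tau outlier rejection (0 if no nonzero
#' counts remain); the noise rate divides it by the mean depth over the
#' window.
#'
#' @slot noiseCount integer: background-noise read count.
#' @slot noiseRate numeric in \[0, 1\]: `noiseCount / meanDepth`.
#' @slot kept integer vector: trimmed noise sample (nonzero counts kept).
#' @slot removed integer vector: counts rejected as outliers.
#' @slot windowStart,windowEnd integer: genomic bounds of the window used.
#' @slot meanDepth numeric: mean declared depth over window positions.
#'
#' @seealso [detectOutliers()], [modifiedThompsonTau()]
#' @export
setClass("NoiseEstimate",
  slots = c(
    noiseCount  = "integer",
    noiseRate   = "numeric",
    kept        = "integer",
    removed     = "integer",
    windowStart = "integer",
    windowEnd   = "integer",
    meanDepth   = "numeric"
  )
)

setValidity("NoiseEstimate", function(object) {
  msg <- character(0)
  if (length(object@kept) && object@noiseCount != max(object@kept))
    msg <- c(msg, "noiseCount must equal max(kept) when kept is nonempty")
  if (!length(object@kept) && object@noiseCount != 0L)
    msg <- c(msg, "noiseCount must be 0 when kept is empty")
  if (object@noiseRate < 0 || object@noiseRate > 1)
    msg <- c(msg, "noiseRate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CallerConfig: tunable parameters of the caller
#'
#' All thresholds of the statistical step and the four quality filters,
#' plus simulator-independent run options. Defaults are the method's
#' standard settings: alpha 0.001, 200-bp window, noise multiplier 2,
#' mean Phred strictly greater than 20, Phred SD strictly below 7, strand
#' balance within \[0.30, 0.70\] inclusive.
#'
#' @slot alpha numeric in (0,1): two-tailed risk of the Thompson Tau test.
#' @slot windowBp integer: total window span in bp (200 = +/-100 bp).
#' @slot noiseMultiplier numeric: factor on the noise rate in the
#'   allele-fraction filter.
#' @slot minMeanPhred numeric: mean base quality must exceed this.
#' @slot maxPhredSd numeric: base-quality SD must be below this.
#' @slot strandBalanceLow,strandBalanceHigh numeric: inclusive bounds on
#'   the forward-read fraction of the variant.
#' @slot vafMinSnv,vafMinIndel numeric: optional reporting cutoffs on the
#'   allele fraction of emitted SNV / indel records (`NA` = off).
#' @slot includeCenter logical: include the candidate position's own
#'   alternative count in its noise sample (default `FALSE`).
#' @slot passOnly logical: drop filter-failing calls from output.
#'
#' @seealso [callerConfig()], [callVariants()]
#' @export
setClass("CallerConfig",
  slots = c(
    alpha             = "numeric",
    windowBp          = "integer",
    noiseMultiplier   = "numeric",
    minMeanPhred      = "numeric",
    maxPhredSd        = "numeric",
    strandBalanceLow  = "numeric",
    strandBalanceHigh = "numeric",
    vafMinSnv         = "numeric",
    vafMinIndel       = "numeric",
    includeCenter     = "logical",
    passOnly          = "logical"
  ),
  prototype = list(
    alpha = 0.001, windowBp = 200L, noiseMultiplier = 2,
    minMeanPhred = 20, maxPhredSd = 7,
    strandBalanceLow = 0.30, strandBalanceHigh = 0.70,
    vafMinSnv = NA_real_, vafMinIndel = NA_real_,
    includeCenter = FALSE, passOnly = FALSE
  )
)

setValidity("CallerConfig", function(object) {
  msg <- character(0)
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@windowBp < 1L)
    msg <- c(msg, "windowBp must be positive")
  if (object@noiseMultiplier < 0)
    msg <- c(msg, "noiseMultiplier must be non-negative")
  if (!(object@strandBalanceLow >= 0 &&
        object@strandBalanceLow < object@strandBalanceHigh &&
        object@strandBalanceHigh <= 1))
    msg <- c(msg, "need 0 <= strandBalanceLow < strandBalanceHigh <= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a caller configuration
#'
#' @param alpha two-tailed risk of the modified Thompson Tau test.
#' @param windowBp total noise-window span in bp.
#' @param noiseMultiplier factor on the noise rate in filter (i).
#' @param minMeanPhred strict lower bound on the mean variant Phred score.
#' @param maxPhredSd strict upper bound on the variant Phred SD.
#' @param strandBalanceLow,strandBalanceHigh inclusive bounds on the
#'   forward-strand fraction.
#' @param vafMinSnv,vafMinIndel optional reporting cutoffs (fractions) on
#'   emitted SNV / indel records; `NA` disables them.
#' @param includeCenter include the candidate position's own alternative
#'   count in the noise sample.
#' @param passOnly emit only PASS calls.
#' @return A [CallerConfig-class] object.
#' @examples
#' callerConfig()
#' callerConfig(alpha = 0.01, windowBp = 100)
#' @export
callerConfig <- function(alpha = 0.001, windowBp = 200, noiseMultiplier = 2,
                         minMeanPhred = 20, maxPhredSd = 7,
                         strandBalanceLow = 0.30, strandBalanceHigh = 0.70,
                         vafMinSnv = NA_real_, vafMinIndel = NA_real_,
                         includeCenter = FALSE, passOnly = FALSE) {
  new("CallerConfig", alpha = alpha, windowBp = as.integer(windowBp),
      noiseMultiplier = noiseMultiplier, minMeanPhred = minMeanPhred,
      maxPhredSd = maxPhredSd, strandBalanceLow = strandBalanceLow,
      strandBalanceHigh = strandBalanceHigh,
      vafMinSnv = as.numeric(vafMinSnv), vafMinIndel = as.numeric(vafMinIndel),
      includeCenter = includeCenter, passOnly = passOnly)
}
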