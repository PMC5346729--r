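#' Enumerate candidate variants of a profile
#'
#' Every (position, alternative allele) with at least one supporting read
#' is a candidate; each alternative allele at a multi-allelic position is
#' an independent candidate. Quality summaries use the supporting base
#' qualities (anchor-base qualities for indels); the SD of a single
#' quality value is defined as 0.
#'
#' @param profile a [RegionProfile-class].
#' @return data.frame with columns `pos`, `ref`, `allele`, `count`,
#'   `fwd`, `rev`, `depth`, `vaf`, `meanQual`, `sdQual`.
#' @export
collectCandidates <- function(profile) {
  rows <- list()
  for (k in seq_along(profile@pos)) {
    for (x in profile@alts[[k]]) {
      if (x$count < 1L) next
      dp <- profile@depth[k]
      rows[[length(rows) + 1L]] <- data.frame(
        pos = profile@pos[k], ref = profile@refBase[k], allele = x$allele,
        count = x$count, fwd = x$fwd, rev = x$rev, depth = dp,
        vaf = if (dp > 0L) x$count / dp else 0,
        meanQual = mean(x$quals),
        sdQual = if (x$count > 1L) stats::sd(x$quals) else 0,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(pos = integer(0), ref = character(0),
                      allele = character(0), count = integer(0),
                      fwd = integer(0), rev = integer(0), depth = integer(0),
                      vaf = numeric(0), meanQual = numeric(0),
                      sdQual = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Statistical step: candidate count versus local background noise
#'
#' A candidate is promoted to filtration only when its supporting-read
#' count is strictly higher than the local background-noise count;
#' otherwise it is considered part of the background noise.
#'
#' @param count supporting-read count of the candidate.
#' @param noise a [NoiseEstimate-class] for the candidate's position.
#' @return logical.
#' @export
statisticalStep <- function(count, noise) {
  count > noise@noiseCount
}

#' Quality filtration of a candidate that passed the statistical step
#'
#' Evaluates all four criteria and reports every failure:
#' (i) the allele fraction must be greater than `noiseMultiplier` times
#' the local noise rate (`low_ratio_vs_noise`); (ii) the mean supporting
#' Phred score must be strictly greater than `minMeanPhred`
#' (`low_mean_qual`); (iii) its SD must be strictly below `maxPhredSd`
#' (`high_qual_sd`); (iv) the forward-strand fraction of the supporting
#' reads must lie within `[strandBalanceLow, strandBalanceHigh]`
#' inclusive (`strand_imbalance`).
#'
#' @param candidate list or one-row data.frame with fields `vaf`, `fwd`,
#'   `count`, `meanQual`, `sdQual`.
#' @param noise a [NoiseEstimate-class].
#' @param config a [CallerConfig-class].
#' @return `"PASS"` or a character vector of failed-filter tags.
#' @export
applyFilters <- function(candidate, noise, config = callerConfig()) {
  fails <- character(0)
  if (!(candidate$vaf > config@noiseMultiplier * noise@noiseRate))
    fails <- c(fails, "low_ratio_vs_noise")
  if (!(candidate$meanQual > config@minMeanPhred))
    fails <- c(fails, "low_mean_qual")
  if (!(candidate$sdQual < config@maxPhredSd))
    fails <- c(fails, "high_qual_sd")
  fwdFrac <- candidate$fwd / candidate$count
  if (!(fwdFrac >= config@strandBalanceLow &&
        fwdFrac <= config@strandBalanceHigh))
    fails <- c(fails, "strand_imbalance")
  if (length(fails)) fails else "PASS"
}

.emptyCalls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), depth = integer(0), altCount = integer(0),
             vaf = numeric(0), fwdCount = integer(0), revCount = integer(0),
             meanQual = numeric(0), sdQual = numeric(0),
             noiseCount = integer(0), noiseRate = numeric(0),
             windowStart = integer(0), windowEnd = integer(0),
             filter = character(0), stringsAsFactors = FALSE)
}

#' Call variants on parsed region profiles
#'
#' For every candidate: estimate the local background noise in a window
#' centered on its position, apply the statistical step (count strictly
#' above the noise count), then the four quality filters. Candidates that
#' fail the statistical step produce no call; candidates that fail
#' filters are retained with their failed-filter tags unless
#' `config@passOnly`. Optional reporting cutoffs `vafMinSnv` /
#' `vafMinIndel` drop emitted records below the given allele fraction.
#'
#' @param profiles list of [RegionProfile-class] (or a single profile).
#' @param config a [CallerConfig-class].
#' @return data.frame of calls sorted by chromosome and position, with
#'   columns `chrom`, `pos`, `ref`, `alt`, `depth`, `altCount`, `vaf`,
#'   `fwdCount`, `revCount`, `meanQual`, `sdQual`, `noiseCount`,
#'   `noiseRate`, `windowStart`, `windowEnd`, `filter`.
#' @examples
#' sim <- simulateProfiles(simulationConfig(
#'   regions = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200)),
#'   depth = 1000, errorRate = 0.001,
#'   variants = data.frame(chrom = "chr1", pos = 100, alt = "T", vaf = 0.05),
#'   seed = 1))
#' calls <- callVariants(sim$profiles)
#' subset(calls, filter == "PASS")
#' @export
callVariants <- function(profiles, config = callerConfig()) {
  if (is(profiles, "RegionProfile")) profiles <- list(profiles)
  out <- list()
  for (profile in profiles) {
    cand <- collectCandidates(profile)
    if (!nrow(cand)) next
    chrom <- as.character(GenomicRanges::seqnames(profile@region))
    noiseCache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(cand))) {
      key <- as.character(cand$pos[i])
      noise <- get0(key, envir = noiseCache)
      if (is.null(noise)) {
        noise <- localBackgroundNoise(profile, cand$pos[i],
                                      windowBp = config@windowBp,
                                      alpha = config@alpha,
                                      includeCenter = config@includeCenter)
        assign(key, noise, envir = noiseCache)
      }
      if (!statisticalStep(cand$count[i], noise)) next
      status <- applyFilters(cand[i, ], noise, config)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, pos = cand$pos[i], ref = cand$ref[i],
        alt = cand$allele[i], depth = cand$depth[i],
        altCount = cand$count[i], vaf = cand$vaf[i],
        fwdCount = cand$fwd[i], revCount = cand$rev[i],
        meanQual = cand$meanQual[i], sdQual = cand$sdQual[i],
        noiseCount = noise@noiseCount, noiseRate = noise@noiseRate,
        windowStart = noise@windowStart, windowEnd = noise@windowEnd,
        filter = paste(status, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyCalls())
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  isIndel <- substr(calls$alt, 1L, 1L) %in% c("+", "-")
  if (!is.na(config@vafMinSnv))
    calls <- calls[isIndel | calls$vaf >= config@vafMinSnv, , drop = FALSE]
  isIndel <- substr(calls$alt, 1L, 1L) %in% c("+", "-")
  if (!is.na(config@vafMinIndel))
    calls <- calls[!isIndel | calls$vaf >= config@vafMinIndel, , drop = FALSE]
  if (config@passOnly)
    calls <- calls[calls$filter == "PASS", , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

.lodAtPosition <- function(profile, k, config) {
  noise <- localBackgroundNoise(profile, profile@pos[k],
                                windowBp = config@windowBp,
                                alpha = config@alpha,
                                includeCenter = config@includeCenter)
  dp <- profile@depth[k]
  lod <- if (dp > 0L)
    max(config@noiseMultiplier * noise@noiseRate, (noise@noiseCount + 1) / dp)
  else NA_real_
  c(lod = min(lod, 1), noiseRate = noise@noiseRate, depth = dp)
}

#' Limit-of-detection report (minimum detectable allele ratio)
#'
#' For each covered position the minimum detectable allele ratio is the
#' smallest allele fraction that would clear both the statistical step
#' and the allele-fraction filter:
#' `max(noiseMultiplier * noiseRate, (noiseCount + 1) / depth)`.
#' Per region, the mean and the worst-case (maximum) across positions are
#' reported, together with mean depth and mean noise rate.
#'
#' @param profiles list of [RegionProfile-class].
#' @param config a [CallerConfig-class].
#' @param positions optional data.frame with columns `chrom`, `pos` to
#'   report single positions instead of whole regions.
#' @param perPosition when `TRUE`, return one row per covered position.
#' @return data.frame with columns `target`, `chrom`, `start`, `end`,
#'   `mean_depth`, `mean_noise_rate`, `lod_mean`, `lod_max` (region mode),
#'   or per-position columns `chrom`, `pos`, `depth`, `noise_rate`, `lod`.
#' @export
lodReport <- function(profiles, config = callerConfig(), positions = NULL,
                      perPosition = FALSE) {
  if (is(profiles, "RegionProfile")) profiles <- list(profiles)
  if (!is.null(positions)) {
    rows <- lapply(seq_len(nrow(positions)), function(i) {
      hit <- .findProfile(profiles, positions$chrom[i], positions$pos[i])
      k <- match(positions$pos[i], hit@pos)
      if (is.na(k))
        stop(sprintf("position %s:%d not covered by the pileup",
                     positions$chrom[i], positions$pos[i]), call. = FALSE)
      v <- .lodAtPosition(hit, k, config)
      data.frame(chrom = positions$chrom[i], pos = positions$pos[i],
                 depth = unname(v["depth"]), noise_rate = unname(v["noiseRate"]),
                 lod = unname(v["lod"]), stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  out <- lapply(profiles, function(profile) {
    n <- length(profile@pos)
    chrom <- as.character(GenomicRanges::seqnames(profile@region))
    label <- S4Vectors::mcols(profile@region)$name
    target <- if (!is.null(label) && !is.na(label)) label else
      sprintf("%s:%d-%d", chrom, GenomicRanges::start(profile@region),
              GenomicRanges::end(profile@region))
    if (n == 0L) {
      reg <- data.frame(target = target, chrom = chrom,
                        start = GenomicRanges::start(profile@region),
                        end = GenomicRanges::end(profile@region),
                        mean_depth = NA_real_, mean_noise_rate = NA_real_,
                        lod_mean = NA_real_, lod_max = NA_real_,
                        stringsAsFactors = FALSE)
      return(if (perPosition) NULL else reg)
    }
    vals <- vapply(seq_len(n), function(k) .lodAtPosition(profile, k, config),
                   numeric(3))
    if (perPosition)
      return(data.frame(chrom = chrom, pos = profile@pos,
                        depth = vals["depth", ],
                        noise_rate = vals["noiseRate", ],
                        lod = vals["lod", ], stringsAsFactors = FALSE))
    data.frame(target = target, chrom = chrom,
               start = GenomicRanges::start(profile@region),
               end = GenomicRanges::end(profile@region),
               mean_depth = mean(vals["depth", ]),
               mean_noise_rate = mean(vals["noiseRate", ]),
               lod_mean = mean(vals["lod", ], na.rm = TRUE),
               lod_max = max(vals["lod", ], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.findProfile <- function(profiles, chrom, pos) {
  for (profile in profiles) {
    r <- profile@region
    if (as.character(GenomicRanges::seqnames(r)) == chrom &&
        pos >= GenomicRanges::start(r) && pos <= GenomicRanges::end(r))
      return(profile)
  }
  stop(sprintf("position %s:%d not covered by any region", chrom, pos),
       call. = FALSE)
}

#' Single-position metrics query
#'
#' Reports the major sequencing features of one genomic position:
#' sequencing depth, reference and (if present) major alternative allele,
#' forward/reverse counts of the alternative reads, average sequencing
#' quality at the position, and the local background-noise estimate.
#'
#' @param profiles list of [RegionProfile-class].
#' @param chrom chromosome name.
#' @param pos 1-based position; must be covered by a parsed region.
#' @param config a [CallerConfig-class].
#' @return named list with fields `chrom`, `pos`, `depth`, `ref`, `alt`
#'   (`NA` if no alternative reads), `altCount`, `altFwd`, `altRev`,
#'   `altVaf`, `meanQual`, `noise` (a [NoiseEstimate-class]).
#' @export
positionReport <- function(profiles, chrom, pos, config = callerConfig()) {
  if (is(profiles, "RegionProfile")) profiles <- list(profiles)
  profile <- .findProfile(profiles, chrom, pos)
  k <- match(pos, profile@pos)
  if (is.na(k))
    stop(sprintf("position %s:%d not covered by the pileup", chrom, pos),
         call. = FALSE)
  noise <- localBackgroundNoise(profile, pos, windowBp = config@windowBp,
                                alpha = config@alpha,
                                includeCenter = config@includeCenter)
  a <- profile@alts[[k]]
  allQuals <- c(profile@refQuals[[k]],
                unlist(lapply(a, `[[`, "quals"), use.names = FALSE))
  rep <- list(chrom = chrom, pos = pos, depth = profile@depth[k],
              ref = profile@refBase[k], alt = NA_character_,
              altCount = 0L, altFwd = 0L, altRev = 0L, altVaf = 0,
              meanQual = if (length(allQuals)) mean(allQuals) else NA_real_,
              noise = noise)
  if (length(a)) {
    counts <- vapply(a, `[[`, integer(1), "count")
    top <- a[[which.max(counts)]]
    rep$alt <- top$allele
    rep$altCount <- top$count
    rep$altFwd <- top$fwd
    rep$altRev <- top$rev
    rep$altVaf <- if (profile@depth[k] > 0L) top$count / profile@depth[k] else 0
  }
  rep
}
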