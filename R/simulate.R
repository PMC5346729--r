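## evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

.drawQuals <- function(n, mean, sd, qmin, qmax) {
  if (n == 0L) return(integer(0))
  as.integer(round(pmin(pmax(stats::rnorm(n, mean, sd), qmin), qmax)))
}

#' Simulation configuration for synthetic pileups
#'
#' Describes the study conditions emulated by the simulator: target
#' regions, mean depth (fixed or Poisson-distributed per position), a
#' uniform per-base substitution error rate (errors spread uniformly over
#' the three non-reference bases and both strands), Phred-quality models
#' for true and error base calls, and a set of injected variants with
#' target allele fraction. Injected variant reads are split across
#' strands deterministically at the configured forward fraction, so the
#' strand-balance filter responds to the configured bias rather than to
#' sampling noise.
#'
#' @param regions `GRanges` of regions to simulate.
#' @param depth mean target depth (reads).
#' @param depthModel `"fixed"` or `"poisson"` (Poisson around `depth`).
#' @param errorRate per-base substitution error probability, in
#'   \[0, 0.05).
#' @param trueQualMean,trueQualSd Phred model of correct base calls
#'   (defaults 35, 3, clipped to `qualMin..qualMax`).
#' @param errQualMean,errQualSd Phred model of error base calls
#'   (defaults 25, 6).
#' @param qualMin,qualMax clipping bounds of simulated Phred scores.
#' @param variants optional data.frame with columns `chrom`, `pos`,
#'   `alt`, `vaf` and optional `strandFraction` (default 0.5),
#'   `qualMean`, `qualSd` (default: the true-base model). `alt` is a base
#'   (`"T"`), an insertion (`"+AG"`), a deletion of the next N reference
#'   bases (`"-2"`), or `NA` for an arbitrary substitution.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(regions, depth = 1000, depthModel = c("fixed", "poisson"),
                             errorRate = 0.001, trueQualMean = 35, trueQualSd = 3,
                             errQualMean = 25, errQualSd = 6,
                             qualMin = 2, qualMax = 41,
                             variants = NULL, seed = 1) {
  depthModel <- match.arg(depthModel)
  if (errorRate < 0 || errorRate >= 0.05)
    stop("errorRate must lie in [0, 0.05)", call. = FALSE)
  if (!is.null(variants) && nrow(variants)) {
    if (any(variants$vaf <= 0 | variants$vaf > 1))
      stop("variant VAF must lie in (0, 1]", call. = FALSE)
    if (is.null(variants$strandFraction)) variants$strandFraction <- 0.5
    if (is.null(variants$qualMean)) variants$qualMean <- NA_real_
    if (is.null(variants$qualSd)) variants$qualSd <- NA_real_
  }
  structure(list(regions = regions, depth = depth, depthModel = depthModel,
                 errorRate = errorRate, trueQualMean = trueQualMean,
                 trueQualSd = trueQualSd, errQualMean = errQualMean,
                 errQualSd = errQualSd, qualMin = qualMin, qualMax = qualMax,
                 variants = variants, seed = seed),
            class = "SimulationConfig")
}

.emptyTruth <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), targetVaf = numeric(0), depth = integer(0),
             realizedCount = integer(0), realizedVaf = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate region profiles with known truth
#'
#' Generates one [RegionProfile-class] per configured region. Per
#' position, the depth is drawn from the depth model, error reads
#' binomially at the error rate (uniform over the three non-reference
#' bases, Bernoulli strands), and each injected variant binomially at its
#' target allele fraction with its strand and quality profile. The truth
#' table records the realized supporting-read count of every injected
#' variant.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `profiles` (list of
#'   [RegionProfile-class]) and `truth` (data.frame with columns `chrom`,
#'   `pos`, `ref`, `alt`, `targetVaf`, `depth`, `realizedCount`,
#'   `realizedVaf`).
#' @export
simulateProfiles <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    bases <- c("A", "C", "G", "T")
    profiles <- vector("list", length(config$regions))
    truthRows <- list()
    for (ri in seq_along(config$regions)) {
      r <- config$regions[ri]
      chrom <- as.character(GenomicRanges::seqnames(r))
      pos <- GenomicRanges::start(r):GenomicRanges::end(r)
      npos <- length(pos)
      refBase <- sample(bases, npos, replace = TRUE)
      depth <- if (config$depthModel == "fixed")
        rep(as.integer(round(config$depth)), npos)
      else stats::rpois(npos, config$depth)
      vtab <- config$variants
      if (!is.null(vtab))
        vtab <- vtab[vtab$chrom == chrom, , drop = FALSE]
      if (!is.null(vtab) && nrow(vtab) &&
          any(vtab$pos < pos[1] | vtab$pos > pos[npos]))
        stop("injected variant position outside the simulated regions",
             call. = FALSE)
      vcount <- integer(npos)      # variant reads at anchor
      valt <- character(npos)      # resolved allele key
      vfwd <- integer(npos)
      vq <- vector("list", npos)
      starExtra <- integer(npos)   # deletion-spanning '*' placeholders
      if (!is.null(vtab) && nrow(vtab)) {
        for (vi in seq_len(nrow(vtab))) {
          k <- match(vtab$pos[vi], pos)
          alt <- vtab$alt[vi]
          if (is.na(alt)) alt <- setdiff(bases, refBase[k])[1]
          ## the simulator owns the reference: avoid colliding with a
          ## requested substitution allele
          if (alt %in% bases && refBase[k] == alt)
            refBase[k] <- sample(setdiff(bases, alt), 1L)
          if (grepl("^-[0-9]+$", alt)) {
            len <- as.integer(substr(alt, 2L, nchar(alt)))
            if (k + len > npos)
              stop("deletion extends beyond the simulated region",
                   call. = FALSE)
            alt <- paste0("-", paste(refBase[(k + 1L):(k + len)],
                                     collapse = ""))
          }
          if (alt == refBase[k])
            stop("injected alt equals the reference base", call. = FALSE)
          cnt <- stats::rbinom(1L, depth[k], vtab$vaf[vi])
          qm <- vtab$qualMean[vi]; qsd <- vtab$qualSd[vi]
          if (is.na(qm)) qm <- config$trueQualMean
          if (is.na(qsd)) qsd <- config$trueQualSd
          vcount[k] <- cnt
          valt[k] <- alt
          vfwd[k] <- as.integer(round(cnt * vtab$strandFraction[vi]))
          vq[[k]] <- .drawQuals(cnt, qm, qsd, config$qualMin, config$qualMax)
          if (substr(alt, 1L, 1L) == "-") {
            len <- nchar(alt) - 1L
            span <- (k + 1L):(k + len)
            starExtra[span] <- pmax(starExtra[span], cnt)
          }
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            chrom = chrom, pos = pos[k], ref = refBase[k], alt = alt,
            targetVaf = vtab$vaf[vi], depth = depth[k], realizedCount = cnt,
            realizedVaf = if (depth[k] > 0L) cnt / depth[k] else 0,
            stringsAsFactors = FALSE)
        }
      }
      errN <- stats::rbinom(npos, pmax(depth - vcount - starExtra, 0L),
                            config$errorRate)
      refCount <- integer(npos); refQuals <- vector("list", npos)
      starCount <- integer(npos); alts <- vector("list", npos)
      for (k in seq_len(npos)) {
        star <- min(starExtra[k], depth[k])
        e <- min(errN[k], max(depth[k] - vcount[k] - star, 0L))
        obs <- list()
        if (e > 0L) {
          ## error bases never collide with an injected substitution, so
          ## the truth table's realized count is exactly recoverable from
          ## the emitted pileup
          pool <- setdiff(bases, c(refBase[k],
                                   if (vcount[k] > 0L) valt[k]))
          errBases <- sample(pool, e, replace = TRUE)
          for (b in unique(errBases)) {
            cnt <- sum(errBases == b)
            obs[[length(obs) + 1L]] <- list(
              allele = b, count = cnt,
              fwd = stats::rbinom(1L, cnt, 0.5), rev = 0L,
              quals = .drawQuals(cnt, config$errQualMean, config$errQualSd,
                                 config$qualMin, config$qualMax))
            obs[[length(obs)]]$rev <- cnt - obs[[length(obs)]]$fwd
          }
        }
        isIndel <- FALSE
        if (vcount[k] > 0L) {
          isIndel <- substr(valt[k], 1L, 1L) %in% c("+", "-")
          merged <- FALSE
          for (oi in seq_along(obs)) {
            if (obs[[oi]]$allele == valt[k]) {
              obs[[oi]]$count <- obs[[oi]]$count + vcount[k]
              obs[[oi]]$fwd <- obs[[oi]]$fwd + vfwd[k]
              obs[[oi]]$rev <- obs[[oi]]$rev + (vcount[k] - vfwd[k])
              obs[[oi]]$quals <- c(obs[[oi]]$quals, vq[[k]])
              merged <- TRUE
            }
          }
          if (!merged)
            obs[[length(obs) + 1L]] <- list(
              allele = valt[k], count = vcount[k], fwd = vfwd[k],
              rev = vcount[k] - vfwd[k], quals = vq[[k]])
        }
        ## indel carriers report the anchor reference base as well
        subVar <- if (vcount[k] > 0L && !isIndel) vcount[k] else 0L
        refCount[k] <- max(depth[k] - e - subVar - star, 0L)
        nCarrier <- if (isIndel) vcount[k] else 0L
        nPlain <- refCount[k] - nCarrier
        if (nPlain < 0L) { nCarrier <- refCount[k]; nPlain <- 0L }
        refQuals[[k]] <- c(if (nCarrier > 0L) vq[[k]][seq_len(nCarrier)],
                           .drawQuals(nPlain, config$trueQualMean,
                                      config$trueQualSd, config$qualMin,
                                      config$qualMax))
        starCount[k] <- star
        alts[[k]] <- obs
      }
      profiles[[ri]] <- .newRegionProfile(
        chrom, pos[1], pos[npos], pos, refBase, depth, refCount, refQuals,
        starCount, alts,
        label = if (!is.null(S4Vectors::mcols(r)$name))
          S4Vectors::mcols(r)$name else NA_character_)
    }
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else .emptyTruth()
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate pileup text with a truth table
#'
#' Convenience wrapper around [simulateProfiles()] +
#' [profileToPileup()]: returns (and optionally writes) mpileup-dialect
#' text plus the truth table of injected variants.
#'
#' @param config a [simulationConfig()].
#' @param prefix optional output path prefix; writes `<prefix>.pileup`
#'   and `<prefix>.truth.tsv`.
#' @return list with elements `pileup` (character lines) and `truth`
#'   (data.frame).
#' @export
simulatePileup <- function(config, prefix = NULL) {
  sim <- simulateProfiles(config)
  lines <- unlist(lapply(sim$profiles, profileToPileup), use.names = FALSE)
  if (!is.null(prefix)) {
    writeLines(lines, paste0(prefix, ".pileup"))
    utils::write.table(sim$truth, paste0(prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(pileup = lines, truth = sim$truth)
}

#' In-silico depth downsampling of a region profile
#'
#' Thins every read observation independently with retention probability
#' `fraction`, preserving the strand and quality of retained reads (and
#' the anchor pairing of indel-carrier reads). `fraction = 1` returns the
#' profile unchanged.
#'
#' @param profile a [RegionProfile-class].
#' @param fraction retention probability in (0, 1].
#' @param seed optional integer seed.
#' @return a downsampled [RegionProfile-class].
#' @export
downsampleProfile <- function(profile, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(profile)
  .withSeed(seed, {
    n <- length(profile@pos)
    depth <- integer(n); refCount <- integer(n)
    refQuals <- vector("list", n); starCount <- integer(n)
    alts <- vector("list", n)
    for (k in seq_len(n)) {
      a <- profile@alts[[k]]
      isIndel <- if (length(a))
        vapply(a, function(x) substr(x$allele, 1L, 1L) %in% c("+", "-"),
               logical(1)) else logical(0)
      nCarrier <- sum(vapply(a[isIndel], `[[`, integer(1), "count"))
      newAlts <- list(); anchorQuals <- integer(0); carrierKept <- 0L
      for (oi in seq_along(a)) {
        x <- a[[oi]]
        keep <- stats::runif(x$count) <= fraction
        cnt <- sum(keep)
        if (isIndel[oi]) {
          carrierKept <- carrierKept + cnt
          anchorQuals <- c(anchorQuals, x$quals[keep])
        }
        if (cnt > 0L)
          newAlts[[length(newAlts) + 1L]] <- list(
            allele = x$allele, count = cnt,
            fwd = sum(keep[seq_len(x$fwd)]), rev = sum(keep) - sum(keep[seq_len(x$fwd)]),
            quals = x$quals[keep])
      }
      nPlain <- profile@refCount[k] - nCarrier
      plainQ <- profile@refQuals[[k]][nCarrier + seq_len(max(nPlain, 0L))]
      keepPlain <- stats::runif(length(plainQ)) <= fraction
      star <- stats::rbinom(1L, profile@starCount[k], fraction)
      refCount[k] <- carrierKept + sum(keepPlain)
      refQuals[[k]] <- c(anchorQuals, plainQ[keepPlain])
      starCount[k] <- star
      alts[[k]] <- newAlts
      subKept <- if (length(newAlts))
        sum(vapply(newAlts, function(x)
          if (substr(x$allele, 1L, 1L) %in% c("+", "-")) 0L else x$count,
          integer(1))) else 0L
      depth[k] <- refCount[k] + subKept + star
    }
    r <- profile@region
    .newRegionProfile(as.character(GenomicRanges::seqnames(r)),
                      GenomicRanges::start(r), GenomicRanges::end(r),
                      profile@pos, profile@refBase, depth, refCount,
                      refQuals, starCount, alts,
                      label = if (!is.null(S4Vectors::mcols(r)$name))
                        S4Vectors::mcols(r)$name else NA_character_)
  })
}

## judge a single injected candidate through the full calling criteria
.judgeInjected <- function(profile, pos, allele, config) {
  k <- match(pos, profile@pos)
  if (is.na(k)) return(FALSE)
  obs <- NULL
  for (x in profile@alts[[k]]) if (x$allele == allele) obs <- x
  if (is.null(obs) || obs$count < 1L) return(FALSE)
  noise <- localBackgroundNoise(profile, pos, windowBp = config@windowBp,
                                alpha = config@alpha,
                                includeCenter = config@includeCenter)
  if (!statisticalStep(obs$count, noise)) return(FALSE)
  dp <- profile@depth[k]
  cand <- list(vaf = if (dp > 0L) obs$count / dp else 0, fwd = obs$fwd,
               count = obs$count, meanQual = mean(obs$quals),
               sdQual = if (obs$count > 1L) stats::sd(obs$quals) else 0)
  identical(applyFilters(cand, noise, config), "PASS")
}

#' Coverage-sensitivity benchmark
#'
#' For each (depth bin, allele fraction) cell, simulates `replicates`
#' independent single-region pileups with one injected substitution at
#' the region center and reports the fraction of replicates in which the
#' injected variant is a PASS call. Depth bins are represented by a
#' single simulated depth per bin (defaults: midpoints 100, 225, 450,
#' 800 and 1200 for the bins <150, 150-300, 300-600, 600-1000 and
#' >1000).
#'
#' @param depths named numeric vector: representative simulated depth per
#'   bin; names are the bin labels.
#' @param vafs numeric vector of injected allele fractions.
#' @param replicates simulations per cell (at least 1).
#' @param errorRate per-base substitution error probability.
#' @param config a [CallerConfig-class]; the simulated region spans the
#'   configured noise window around the injected site.
#' @param seed integer master seed; per-replicate seeds are derived from
#'   it.
#' @param file optional path: the table is also written as TSV.
#' @return data.frame with columns `depth_bin`, `depth`, `vaf`,
#'   `replicates`, `detected`, `sensitivity`.
#' @export
sensitivityHarness <- function(depths = c("<150" = 100, "150-300" = 225,
                                          "300-600" = 450, "600-1000" = 800,
                                          ">1000" = 1200),
                               vafs = c(0.01, 0.02, 0.05),
                               replicates = 100, errorRate = 0.001,
                               config = callerConfig(), seed = 1,
                               file = NULL) {
  stopifnot(replicates >= 1)
  cells <- expand.grid(bin = seq_along(depths), vaf = vafs,
                       KEEP.OUT.ATTRS = FALSE)
  width <- config@windowBp + 1L
  center <- as.integer(ceiling(width / 2))
  seeds <- .withSeed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, nrow(cells) * replicates),
           nrow = nrow(cells)))
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    b <- cells$bin[ci]; vaf <- cells$vaf[ci]
    detected <- 0L
    for (rep in seq_len(replicates)) {
      sim <- simulateProfiles(simulationConfig(
        regions = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width)),
        depth = depths[b], errorRate = errorRate,
        variants = data.frame(chrom = "chr1", pos = center, alt = NA,
                              vaf = vaf, stringsAsFactors = FALSE),
        seed = seeds[ci, rep]))
      if (.judgeInjected(sim$profiles[[1]], center, sim$truth$alt[1], config))
        detected <- detected + 1L
    }
    data.frame(depth_bin = names(depths)[b], depth = unname(depths[b]),
               vaf = vaf, replicates = replicates, detected = detected,
               sensitivity = detected / replicates, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$vaf, out$depth), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
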