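## Independent oracles used to cross-check the package implementation.
## They share no code with the package paths they verify.

## Student's t upper quantile by numerical inversion of the t CDF written
## through the regularized incomplete beta function (pbeta), independent
## of stats::qt.
tQuantileOracle <- function(p, df) {
  stopifnot(p > 0.5, p < 1)
  f <- function(t) (1 - 0.5 * pbeta(df / (df + t^2), df / 2, 0.5)) - p
  uniroot(f, c(0, 1e8), tol = 1e-12, maxiter = 5000L)$root
}

## closed-form modified Thompson Tau on top of the quantile oracle
tauOracle <- function(n, alpha) {
  t <- tQuantileOracle(1 - alpha / 2, n - 2)
  t * (n - 1) / (sqrt(n) * sqrt(n - 2 + t^2))
}

## literal step-by-step outlier trimming: recompute mean/SD, test the
## single most-deviant point (ties as a group) against tau * S, repeat
trimOracle <- function(values, alpha) {
  kept <- values
  removed <- values[0]
  repeat {
    n <- length(kept)
    if (n < 3L) break
    s <- sd(kept)
    if (s == 0) break
    d <- abs(kept - mean(kept))
    hit <- d == max(d)
    if (max(d) > tauOracle(n, alpha) * s) {
      removed <- c(removed, kept[hit])
      kept <- kept[!hit]
    } else break
  }
  list(kept = kept, removed = removed)
}

## recheck a PASS call from the raw column data of its profile:
## window extraction, zero stripping, oracle trimming, and all five
## decision predicates, without calling the package's noise/caller path
passOracle <- function(profile, call, config = callerConfig()) {
  pos <- positions(profile)
  k <- match(call$pos, pos)
  obs <- NULL
  for (x in altObservations(profile)[[k]]) if (x$allele == call$alt) obs <- x
  if (is.null(obs)) return(FALSE)
  half <- floor(config@windowBp / 2)
  lo <- max(call$pos - half, GenomicRanges::start(region(profile)))
  hi <- min(call$pos + half, GenomicRanges::end(region(profile)))
  sel <- pos >= lo & pos <= hi
  ac <- altCounts(profile)[sel]
  ac <- ac[pos[sel] != call$pos]
  s <- ac[ac > 0]
  kept <- if (length(s) >= 3) trimOracle(s, config@alpha)$kept else s
  nc <- if (length(kept)) max(kept) else 0
  nr <- nc / mean(depths(profile)[sel])
  dp <- depths(profile)[k]
  vaf <- obs$count / dp
  fwdFrac <- obs$fwd / obs$count
  sdQ <- if (obs$count > 1) sd(obs$quals) else 0
  obs$count > nc &&
    vaf > config@noiseMultiplier * nr &&
    mean(obs$quals) > config@minMeanPhred &&
    sdQ < config@maxPhredSd &&
    fwdFrac >= config@strandBalanceLow &&
    fwdFrac <= config@strandBalanceHigh
}
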