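## programmatic fixtures shared across test files

## one pileup line with the given T-alt count at fixed depth; the alt
## reads are evenly split across strands with Phred 35 ('D' = +33)
mkNoiseLines <- function(altVec, depth = 100L, chrom = "chr1",
                         startPos = 1L) {
  vapply(seq_along(altVec), function(i) {
    c <- altVec[i]
    fwd <- c %/% 2L; rev <- c - fwd
    bases <- paste0(strrep(".", depth - c), strrep("T", fwd),
                    strrep("t", rev))
    paste(chrom, startPos + i - 1L, "A", depth, bases,
          strrep("D", depth), sep = "\t")
  }, character(1))
}

## inject an alternative allele into an existing simulated profile by
## converting `count` reference reads into alt-supporting reads
injectVariant <- function(profile, pos, alt, count, fwd = NULL,
                          quals = NULL) {
  k <- match(pos, positions(profile))
  stopifnot(!is.na(k), refCounts(profile)[k] >= count)
  if (is.null(fwd)) fwd <- count %/% 2L
  if (is.null(quals)) quals <- rep(35L, count)
  rq <- profile@refQuals[[k]]
  profile@refQuals[[k]] <- rq[seq_len(length(rq) - count)]
  profile@refCount[k] <- profile@refCount[k] - as.integer(count)
  profile@alts[[k]] <- c(profile@alts[[k]], list(list(
    allele = alt, count = as.integer(count), fwd = as.integer(fwd),
    rev = as.integer(count - fwd), quals = as.integer(quals))))
  methods::validObject(profile)
  profile
}

simpleRegion <- function(width = 201L, chrom = "chr1", start = 1L) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start, start + width - 1L))
}
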