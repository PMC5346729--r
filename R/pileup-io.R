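## --- samtools mpileup text decoding -------------------------------------
##
## Base-string codes handled: '.'/',' reference fwd/rev; 'ACGTN'/'acgtn'
## mismatch fwd/rev; '^q' read start (next char = mapping quality, skipped);
## '$' read end (ignored); '+N<seq>'/'-N<seq>' insertion/deletion attached
## to the preceding read (no quality slot of its own; strand from the case
## of <seq>, quality = anchor-base quality); '*' deleted-base placeholder
## (consumes a quality slot, belongs to no allele). Qualities are Phred+33.
## Reads below samtools' base-quality floor (-Q, default 13) may already be
## absent from the pileup; no further quality floor is applied here.

.parseErr <- function(lineno, what) {
  stop(sprintf("pileup parse error at line %d: %s", lineno, what),
       call. = FALSE)
}

.decodeColumn <- function(bases, quals, lineno) {
  qs <- utf8ToInt(quals) - 33L
  if (any(qs < 0L))
    .parseErr(lineno, "quality character below Phred+33 range")
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L; qi <- 0L
  refFwd <- 0L; refRev <- 0L; star <- 0L
  refQuals <- integer(n)
  nref <- 0L
  alts <- list()
  lastQ <- 0L
  upd <- function(key, fwd, qual) {
    a <- alts[[key]]
    if (is.null(a))
      a <- list(allele = key, count = 0L, fwd = 0L, rev = 0L,
                quals = integer(0))
    a$count <- a$count + 1L
    if (fwd) a$fwd <- a$fwd + 1L else a$rev <- a$rev + 1L
    a$quals <- c(a$quals, qual)
    alts[[key]] <<- a
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n) .parseErr(lineno, "dangling read-start marker '^'")
      i <- i + 2L
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      qi <- qi + 1L
      if (qi > length(qs)) .parseErr(lineno, "more base calls than qualities")
      lastQ <- qs[qi]
      if (ch == ".") refFwd <- refFwd + 1L else refRev <- refRev + 1L
      nref <- nref + 1L
      refQuals[nref] <- lastQ
      i <- i + 1L
    } else if (ch == "*") {
      qi <- qi + 1L
      if (qi > length(qs)) .parseErr(lineno, "more base calls than qualities")
      lastQ <- qs[qi]
      star <- star + 1L
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      ndig <- 0L
      while (j <= n && chars[j] %in% c("0","1","2","3","4","5","6","7","8","9")) {
        ndig <- ndig + 1L; j <- j + 1L
      }
      if (ndig == 0L) .parseErr(lineno, sprintf("indel code '%s' without length", ch))
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) .parseErr(lineno, "indel sequence truncated")
      seqChars <- chars[j:(j + len - 1L)]
      if (!all(toupper(seqChars) %in% c("A","C","G","T","N")))
        .parseErr(lineno, "indel sequence contains invalid characters")
      fwd <- toupper(seqChars[1L]) == seqChars[1L]
      upd(paste0(ch, paste(toupper(seqChars), collapse = "")), fwd, lastQ)
      i <- j + len
    } else if (toupper(ch) %in% c("A", "C", "G", "T")) {
      qi <- qi + 1L
      if (qi > length(qs)) .parseErr(lineno, "more base calls than qualities")
      lastQ <- qs[qi]
      upd(toupper(ch), ch == toupper(ch), lastQ)
      i <- i + 1L
    } else if (toupper(ch) == "N") {
      ## ambiguous call: consumes depth and a quality slot, not a variant
      qi <- qi + 1L
      if (qi > length(qs)) .parseErr(lineno, "more base calls than qualities")
      lastQ <- qs[qi]
      star <- star + 1L
      i <- i + 1L
    } else {
      .parseErr(lineno, sprintf("unknown base code '%s'", ch))
    }
  }
  if (qi != length(qs))
    .parseErr(lineno, sprintf(
      "base/quality length mismatch after code stripping (%d calls, %d qualities)",
      qi, length(qs)))
  list(refCount = refFwd + refRev, refQuals = refQuals[seq_len(nref)],
       starCount = star, alts = unname(alts))
}

.newRegionProfile <- function(chrom, start, end, pos, refBase, depth,
                              refCount, refQuals, starCount, alts,
                              label = NA_character_) {
  rg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.na(label)) S4Vectors::mcols(rg)$name <- label
  ## canonical per-position allele order (indels first, then alphabetical)
  ## so that profiles compare equal independently of discovery order
  alts <- lapply(alts, function(a) {
    if (length(a) < 2L) return(a)
    keys <- vapply(a, `[[`, character(1), "allele")
    a[order(!substr(keys, 1L, 1L) %in% c("+", "-"), keys)]
  })
  new("RegionProfile", region = rg, pos = as.integer(pos),
      refBase = refBase, depth = as.integer(depth),
      refCount = as.integer(refCount), refQuals = refQuals,
      starCount = as.integer(starCount), alts = alts)
}

#' Parse samtools mpileup text into region profiles
#'
#' Reads the six-column samtools mpileup dialect (chrom, position,
#' reference base, depth, base string, Phred+33 qualities; an optional
#' seventh mapping-quality column is ignored) and decodes each line into a
#' pileup column. Lines are grouped into one [RegionProfile-class] per
#' target region; positions outside every requested region are dropped.
#'
#' At positions with reference base `N`, every called base counts as an
#' alternative observation.
#'
#' @param input path to a pileup file, or a character vector of pileup
#'   lines.
#' @param regions optional `GRanges` of target regions (e.g. from
#'   [parseBed()]); when `NULL`, one region per chromosome spanning the
#'   observed positions is used.
#' @return list of [RegionProfile-class] objects, one per region that has
#'   at least the region defined (possibly with zero covered positions).
#' @examples
#' lines <- c("chr1\t100\tA\t4\t..Tt\tIIII", "chr1\t101\tC\t4\t....\tIIII")
#' profs <- parsePileup(lines)
#' altCounts(profs[[1]])
#' @export
parsePileup <- function(input, regions = NULL) {
  lines <- if (length(input) == 1L && !grepl("\t", input) && file.exists(input))
    readLines(input) else input
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  nl <- length(lines)
  chrom <- character(nl); pos <- integer(nl); ref <- character(nl)
  depth <- integer(nl)
  cols <- vector("list", nl)
  flds <- strsplit(lines, "[ \t]+")
  for (k in seq_len(nl)) {
    f <- flds[[k]]
    if (length(f) < 6L && !(length(f) >= 4L && f[4] == "0"))
      .parseErr(lineno[k], sprintf("expected 6 columns, found %d", length(f)))
    p <- suppressWarnings(as.integer(f[2]))
    d <- suppressWarnings(as.integer(f[4]))
    if (is.na(p) || is.na(d))
      .parseErr(lineno[k], "non-integer position or depth")
    rb <- toupper(f[3])
    if (!rb %in% c("A", "C", "G", "T", "N"))
      .parseErr(lineno[k], sprintf("invalid reference base '%s'", f[3]))
    chrom[k] <- f[1]; pos[k] <- p; ref[k] <- rb; depth[k] <- d
    cols[[k]] <- if (d == 0L || (length(f) >= 6L && f[5] == "*" && f[6] == "*"))
      list(refCount = 0L, refQuals = integer(0), starCount = 0L, alts = list())
    else
      .decodeColumn(f[5], f[6], lineno[k])
  }
  if (is.null(regions)) {
    if (nl == 0L) return(list())
    regions <- GenomicRanges::GRanges(
      unique(chrom),
      IRanges::IRanges(
        vapply(unique(chrom), function(cc) min(pos[chrom == cc]), integer(1)),
        vapply(unique(chrom), function(cc) max(pos[chrom == cc]), integer(1))))
  }
  out <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    rc <- as.character(GenomicRanges::seqnames(r))
    rs <- GenomicRanges::start(r); re <- GenomicRanges::end(r)
    sel <- which(chrom == rc & pos >= rs & pos <= re)
    if (length(sel) > 1L && any(diff(pos[sel]) <= 0L))
      .parseErr(lineno[sel[which(diff(pos[sel]) <= 0L)[1] + 1L]],
                "positions not strictly increasing within region")
    label <- if (!is.null(S4Vectors::mcols(r)$name))
      S4Vectors::mcols(r)$name else NA_character_
    out[[ri]] <- .newRegionProfile(
      rc, rs, re, pos[sel], ref[sel], depth[sel],
      vapply(cols[sel], `[[`, integer(1), "refCount"),
      lapply(cols[sel], `[[`, "refQuals"),
      vapply(cols[sel], `[[`, integer(1), "starCount"),
      lapply(cols[sel], `[[`, "alts"),
      label = label)
  }
  out
}

#' Parse a BED file of target regions
#'
#' Accepts BED3+ (0-based half-open); coordinates are converted to 1-based
#' inclusive ranges. An optional fourth column becomes the region label.
#'
#' @param input path to a BED file or a character vector of BED lines.
#' @return `GRanges`, with a `name` metadata column when labels are
#'   present.
#' @examples
#' parseBed("chr1\t99\t200\texon1")
#' @export
parseBed <- function(input) {
  lines <- if (length(input) == 1L && !grepl("\t|\n", input) && file.exists(input))
    readLines(input) else input
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  flds <- strsplit(trimws(lines), "[ \t]+")
  for (k in seq_along(flds)) {
    f <- flds[[k]]
    if (length(f) < 3L)
      stop(sprintf("BED line %d: fewer than 3 columns", k), call. = FALSE)
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[3]))
      stop(sprintf("BED line %d: non-integer coordinates", k), call. = FALSE)
    if (as.numeric(f[3]) <= as.numeric(f[2]))
      stop(sprintf("BED line %d: empty interval (end <= start)", k),
           call. = FALSE)
  }
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(vapply(flds, paste, character(1), collapse = "\t"), tmp)
  gr <- rtracklayer::import(tmp, format = "bed")
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, intersect(
    "name", colnames(S4Vectors::mcols(gr))), drop = FALSE]
  gr
}

## --- serialization (round-trip support for simulated profiles) ----------

.phredChar <- function(q) intToUtf8(pmin(pmax(q, 0L), 93L) + 33L, multiple = FALSE)

#' Serialize a region profile back to mpileup text
#'
#' Inverse of [parsePileup()] for profiles built by the simulator: emits
#' one six-column mpileup line per position. Indel-carrier anchor reads
#' are emitted first within a column (using the indel allele's qualities),
#' then plain reference reads, substitutions, and deleted-base
#' placeholders.
#'
#' @param profile a [RegionProfile-class].
#' @return character vector of pileup lines.
#' @export
profileToPileup <- function(profile) {
  chrom <- as.character(GenomicRanges::seqnames(profile@region))
  n <- length(profile@pos)
  out <- character(n)
  for (k in seq_len(n)) {
    a <- profile@alts[[k]]
    isIndel <- if (length(a))
      vapply(a, function(x) substr(x$allele, 1L, 1L) %in% c("+", "-"),
             logical(1)) else logical(0)
    bases <- character(0); quals <- integer(0)
    ## indel carriers: anchor ref base + indel code, anchor quality
    for (x in a[isIndel]) {
      seqs <- substr(x$allele, 2L, nchar(x$allele))
      lenTag <- nchar(seqs)
      for (j in seq_len(x$count)) {
        fwd <- j <= x$fwd
        bases <- c(bases,
                   paste0(if (fwd) "." else ",",
                          substr(x$allele, 1L, 1L), lenTag,
                          if (fwd) seqs else tolower(seqs)))
        quals <- c(quals, x$quals[j])
      }
    }
    nCarrier <- sum(vapply(a[isIndel], `[[`, integer(1), "count"))
    nPlain <- profile@refCount[k] - nCarrier
    if (nPlain < 0L)
      stop("more indel-carrier reads than reference reads at position ",
           profile@pos[k], call. = FALSE)
    plainQ <- profile@refQuals[[k]][nCarrier + seq_len(nPlain)]
    bases <- c(bases, rep(".", nPlain))
    quals <- c(quals, plainQ)
    for (x in a[!isIndel]) {
      bases <- c(bases, rep(c(x$allele, tolower(x$allele)),
                            c(x$fwd, x$rev)))
      quals <- c(quals, x$quals)
    }
    if (profile@starCount[k] > 0L) {
      bases <- c(bases, rep("*", profile@starCount[k]))
      quals <- c(quals, rep(30L, profile@starCount[k]))
    }
    out[k] <- if (length(quals) == 0L)
      paste(chrom, profile@pos[k], profile@refBase[k], profile@depth[k],
            "*", "*", sep = "\t")
    else
      paste(chrom, profile@pos[k], profile@refBase[k], profile@depth[k],
            paste(bases, collapse = ""), .phredChar(quals), sep = "\t")
  }
  out
}

## --- VCF output ----------------------------------------------------------

.vcfRefAlt <- function(refBase, allele) {
  type <- substr(allele, 1L, 1L)
  if (type == "+") {
    seqs <- substr(allele, 2L, nchar(allele))
    c(refBase, paste0(refBase, seqs))
  } else if (type == "-") {
    seqs <- substr(allele, 2L, nchar(allele))
    c(paste0(refBase, seqs), refBase)
  } else {
    c(refBase, allele)
  }
}

#' Write variant calls as VCF 4.2 text
#'
#' Indels are left-anchored on the preceding reference base (the pileup
#' anchor position). Per-record INFO fields carry depth (`DP`),
#' alternative-read count (`AO`), allele fraction (`AF`), strand counts
#' (`SAF`/`SAR`), mean and SD of supporting base qualities (`MQS`/`SQS`),
#' and the local noise estimate (`NC`, `NR`). The FILTER column is `PASS`
#' or the semicolon-joined failed-filter tags. The full effective
#' parameter set is echoed in `##parameter=` header lines so a run can be
#' reproduced from its output alone.
#'
#' @param calls data.frame from [callVariants()] (possibly empty), sorted
#'   by chromosome then position.
#' @param file optional output path; when `NULL` the lines are only
#'   returned.
#' @param sampleName sample identifier echoed in the header.
#' @param config the [CallerConfig-class] used for calling.
#' @return invisibly, the VCF lines.
#' @export
writeVcfCalls <- function(calls, file = NULL, sampleName = "SAMPLE",
                          config = callerConfig()) {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by chromosome and position", call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=tauvc-%s", as.character(utils::packageVersion("tauvc"))),
    sprintf("##sample=%s", sampleName),
    vapply(names(configAsList(config)), function(k)
      sprintf("##parameter=%s=%s", k, format(configAsList(config)[[k]])),
      character(1)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth at site\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternative-allele read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternative allele fraction (AO/DP)\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads on forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads on reverse strand\">",
    "##INFO=<ID=MQS,Number=1,Type=Float,Description=\"Mean Phred quality of alt-supporting bases\">",
    "##INFO=<ID=SQS,Number=1,Type=Float,Description=\"SD of Phred quality of alt-supporting bases\">",
    "##INFO=<ID=NC,Number=1,Type=Integer,Description=\"Local background-noise read count\">",
    "##INFO=<ID=NR,Number=1,Type=Float,Description=\"Local background-noise rate (NC/mean window depth)\">",
    "##FILTER=<ID=low_ratio_vs_noise,Description=\"Allele fraction not greater than noise_multiplier x noise rate\">",
    "##FILTER=<ID=low_mean_qual,Description=\"Mean supporting Phred quality not greater than min_mean_phred\">",
    "##FILTER=<ID=high_qual_sd,Description=\"Supporting Phred quality SD not below max_phred_sd\">",
    "##FILTER=<ID=strand_imbalance,Description=\"Forward-strand fraction outside the configured balance interval\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    body <- vapply(seq_len(nrow(calls)), function(i) {
      cl <- calls[i, ]
      ra <- .vcfRefAlt(cl$ref, cl$alt)
      info <- sprintf(
        "DP=%d;AO=%d;AF=%s;SAF=%d;SAR=%d;MQS=%s;SQS=%s;NC=%d;NR=%s",
        cl$depth, cl$altCount, format(signif(cl$vaf, 6)),
        cl$fwdCount, cl$revCount, format(signif(cl$meanQual, 6)),
        format(signif(cl$sdQual, 6)), cl$noiseCount,
        format(signif(cl$noiseRate, 6)))
      paste(cl$chrom, cl$pos, ".", ra[1], ra[2], ".", cl$filter, info,
            sep = "\t")
    }, character(1))
  }
  lines <- c(hdr, body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
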