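test_that("all-reference and mixed columns decode per the mpileup encoding", {
  p <- parsePileup("chr1\t100\tA\t10\t..........\tIIIIIIIIII")[[1]]
  expect_equal(positions(p), 100L)
  expect_equal(depths(p), 10L)
  expect_equal(refCounts(p), 10L)
  expect_length(altObservations(p)[[1]], 0L)
  expect_equal(altCounts(p), 0L)

  ## aligned quality characters: '.'x4 take I(40), T/T/t/t take J(41)
  p <- parsePileup("chr1\t100\tA\t10\t....TTtt,,\tIIIIJJJJII")[[1]]
  a <- altObservations(p)[[1]]
  expect_length(a, 1L)
  expect_equal(a[[1]]$allele, "T")
  expect_equal(a[[1]]$count, 4L)
  expect_equal(a[[1]]$fwd, 2L)
  expect_equal(a[[1]]$rev, 2L)
  expect_equal(a[[1]]$quals, c(41L, 41L, 41L, 41L))
  expect_equal(refCounts(p), 6L)

  ## distinct quality characters pin the base/quality alignment
  p <- parsePileup("chr1\t100\tA\t10\t....TTtt,,\tIIIIJKLMII")[[1]]
  expect_equal(altObservations(p)[[1]][[1]]$quals, c(41L, 42L, 43L, 44L))
})

test_that("indel codes attach to the preceding read with its anchor quality", {
  p <- parsePileup("chr1\t100\tA\t3\t..+2AG.\tIJI")[[1]]
  a <- altObservations(p)[[1]]
  expect_length(a, 1L)
  expect_equal(a[[1]]$allele, "+AG")
  expect_equal(a[[1]]$count, 1L)
  expect_equal(a[[1]]$fwd, 1L)
  expect_equal(a[[1]]$quals, 41L)  # anchor '.' consumed 'J'
  expect_equal(refCounts(p), 3L)   # anchor read still counts as reference

  p <- parsePileup("chr1\t100\tA\t3\t.,-2tt.\tIJI")[[1]]
  a <- altObservations(p)[[1]]
  expect_equal(a[[1]]$allele, "-TT")
  expect_equal(a[[1]]$rev, 1L)     # lowercase deleted sequence = reverse strand
})

test_that("read-start/read-end markers never change decoded counts", {
  plain <- parsePileup("chr1\t5\tC\t6\t..TTt,\tIIJJKI")[[1]]
  marked <- parsePileup("chr1\t5\tC\t6\t^F..$TT$t^!,\tIIJJKI")[[1]]
  expect_equal(refCounts(marked), refCounts(plain))
  expect_equal(altObservations(marked), altObservations(plain))
  expect_equal(altCounts(marked), altCounts(plain))
})

test_that("deleted-base placeholders consume depth but no allele", {
  p <- parsePileup("chr1\t7\tG\t5\t..**,\tIIIII")[[1]]
  expect_equal(refCounts(p), 3L)
  expect_equal(altCounts(p), 0L)
  expect_equal(p@starCount, 2L)
})

test_that("malformed pileup lines fail with the offending line number", {
  expect_error(parsePileup("chr1\t100\tA\t10"), "line 1")
  expect_error(parsePileup(c("chr1\t1\tA\t2\t..\tII",
                             "chr1\t2\tA\t2\t...\tII")),
               "line 2")
  expect_error(parsePileup("chr1\t1\tA\t3\t..\tIII"), "mismatch")
  expect_error(parsePileup("chr1\t1\tA\t2\t.x\tII"), "unknown base code")
  expect_error(parsePileup("chr1\tx\tA\t2\t..\tII"), "non-integer")
  ## positions must increase within a region
  expect_error(parsePileup(c("chr1\t10\tA\t1\t.\tI",
                             "chr1\t10\tA\t1\t.\tI")),
               "strictly increasing")
})

test_that("region assignment drops positions outside the requested regions", {
  lines <- c("chr1\t99\tA\t1\t.\tI", "chr1\t100\tA\t1\t.\tI",
             "chr1\t150\tA\t1\t.\tI", "chr1\t201\tA\t1\t.\tI",
             "chr2\t100\tA\t1\t.\tI")
  regions <- parseBed(c("chr1\t99\t200\texon1"))
  profs <- parsePileup(lines, regions)
  expect_length(profs, 1L)
  expect_equal(positions(profs[[1]]), c(100L, 150L))
  expect_equal(S4Vectors::mcols(region(profs[[1]]))$name, "exon1")
})

test_that("BED parsing converts to 1-based inclusive coordinates", {
  gr <- parseBed("chr1\t99\t200\texon1")
  expect_equal(GenomicRanges::start(gr), 100L)
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(S4Vectors::mcols(gr)$name, "exon1")
  expect_length(parseBed(character(0)), 0L)
  tmp <- tempfile(); file.create(tmp)
  expect_length(parseBed(tmp), 0L)
  expect_error(parseBed("chr1\t100\t100"), "empty interval")
  expect_error(parseBed("chr1\t1.5\t100"), "non-integer")
  ## space-separated BED is accepted
  expect_equal(GenomicRanges::start(parseBed("chr1 99 200")), 100L)
})

test_that("simulated profiles round-trip through pileup text exactly", {
  for (seed in 1:3) {
    sim <- simulateProfiles(simulationConfig(
      regions = simpleRegion(80), depth = 150, errorRate = 0.004,
      variants = data.frame(chrom = "chr1", pos = c(20L, 40L, 60L),
                            alt = c("T", "+CCA", "-2"),
                            vaf = c(0.1, 0.08, 0.12)),
      seed = seed))
    prof <- sim$profiles[[1]]
    back <- parsePileup(profileToPileup(prof))[[1]]
    expect_equal(back, prof)
  }
})

test_that("decoded counts conserve the declared depth on simulated fixtures", {
  sim <- simulateProfiles(simulationConfig(
    regions = simpleRegion(60), depth = 200, errorRate = 0.005,
    variants = data.frame(chrom = "chr1", pos = 30L, alt = "-3", vaf = 0.2),
    seed = 11))
  prof <- parsePileup(profileToPileup(sim$profiles[[1]]))[[1]]
  subCounts <- vapply(altObservations(prof), function(a) {
    if (!length(a)) return(0L)
    sum(vapply(a, function(x)
      if (substr(x$allele, 1, 1) %in% c("+", "-")) 0L else x$count,
      integer(1)))
  }, integer(1))
  expect_equal(refCounts(prof) + subCounts + prof@starCount, depths(prof))
})

test_that("VCF output carries fields, filters and indel anchoring", {
  cfg <- callerConfig()
  empty <- callVariants(list(), cfg)
  lines <- writeVcfCalls(empty, sampleName = "s0", config = cfg)
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("^##source=tauvc", lines)))
  expect_true(any(grepl("^##parameter=alpha=0.001$", lines)))

  calls <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(100L, 150L), ref = c("A", "A"),
    alt = c("T", "-CT"), depth = c(1000L, 800L), altCount = c(50L, 40L),
    vaf = c(0.05, 0.05), fwdCount = c(25L, 20L), revCount = c(25L, 20L),
    meanQual = c(35, 34), sdQual = c(3, 3), noiseCount = c(2L, 2L),
    noiseRate = c(0.002, 0.0025), windowStart = c(1L, 50L),
    windowEnd = c(200L, 250L), filter = c("PASS", "strand_imbalance"),
    stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".vcf")
  writeVcfCalls(calls, out, sampleName = "s1")
  body <- grep("^[^#]", readLines(out), value = TRUE)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[c(1, 2, 4, 5, 7)], c("chr1", "100", "A", "T", "PASS"))
  expect_match(f[8], "DP=1000;AO=50;AF=0.05")
  ## deletion: REF = anchor + deleted bases, ALT = anchor
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[4], "ACT")
  expect_equal(f2[5], "A")
  expect_equal(f2[7], "strand_imbalance")

  ## standard VCF machinery parses the output
  vcf <- suppressWarnings(VariantAnnotation::readVcf(out))
  expect_equal(unname(as.character(VariantAnnotation::ref(vcf))),
               c("A", "ACT"))
  expect_equal(VariantAnnotation::info(vcf)$AO, c(50L, 40L))

  expect_error(writeVcfCalls(calls[2:1, ], sampleName = "s1"), "sorted")
})
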