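test_that("candidate enumeration covers every alternative allele", {
  altVec <- rep(0L, 201)
  prof <- parsePileup(mkNoiseLines(altVec, depth = 50L))[[1]]
  expect_equal(nrow(collectCandidates(prof)), 0L)

  ## multi-allelic position: T(30) and G(2) are independent candidates,
  ## as are an insertion and an SNV at the same position
  lines <- c("chr1\t10\tA\t50\tTTGg.+2CA....\tIIIIIIIII",
             "chr1\t11\tA\t5\t.....\tIIIII")
  prof <- parsePileup(lines)[[1]]
  cand <- collectCandidates(prof)
  expect_equal(nrow(cand), 3L)
  expect_setequal(cand$allele, c("T", "G", "+CA"))
})

test_that("the statistical step is a strict inequality against the noise count", {
  ne <- new("NoiseEstimate", noiseCount = 2L, noiseRate = 0.002,
            kept = c(1L, 2L), removed = integer(0), windowStart = 1L,
            windowEnd = 200L, meanDepth = 1000)
  expect_true(statisticalStep(50L, ne))
  expect_false(statisticalStep(2L, ne))   # equal count stays in the noise
  ne0 <- new("NoiseEstimate", noiseCount = 0L, noiseRate = 0,
             kept = integer(0), removed = integer(0), windowStart = 1L,
             windowEnd = 200L, meanDepth = 1000)
  expect_true(statisticalStep(1L, ne0))
})

test_that("filters use the worded strict/inclusive boundaries", {
  cfg <- callerConfig()
  ne <- new("NoiseEstimate", noiseCount = 1L, noiseRate = 0.001,
            kept = 1L, removed = integer(0), windowStart = 1L,
            windowEnd = 200L, meanDepth = 1000)
  base <- list(vaf = 0.05, fwd = 25L, count = 50L, meanQual = 35, sdQual = 3)
  expect_equal(applyFilters(base, ne, cfg), "PASS")

  ## mean Phred exactly 20 fails: "greater than 20" is strict
  m <- base; m$meanQual <- 20
  expect_equal(applyFilters(m, ne, cfg), "low_mean_qual")
  ## Phred SD exactly 7 fails: "below 7" is strict
  m <- base; m$sdQual <- 7
  expect_equal(applyFilters(m, ne, cfg), "high_qual_sd")
  ## forward fraction 0.25 fails only the balance criterion
  m <- base; m$fwd <- 12L; m$count <- 48L; m$vaf <- 0.048
  expect_equal(applyFilters(m, ne, cfg), "strand_imbalance")
  ## the 30%/70% bounds themselves are inclusive
  m <- base; m$fwd <- 15L; m$count <- 50L
  expect_equal(applyFilters(m, ne, cfg), "PASS")
  ## allele fraction must exceed twice the noise rate
  m <- base; m$vaf <- 0.002
  expect_equal(applyFilters(m, ne, cfg), "low_ratio_vs_noise")
  ## all failures are reported together
  m <- list(vaf = 0.002, fwd = 0L, count = 4L, meanQual = 15, sdQual = 9)
  expect_setequal(applyFilters(m, ne, cfg),
                  c("low_ratio_vs_noise", "low_mean_qual", "high_qual_sd",
                    "strand_imbalance"))
})

test_that("an injected clean 5% variant at 1000x yields exactly one PASS call", {
  sim <- simulateProfiles(simulationConfig(
    regions = simpleRegion(201), depth = 1000, errorRate = 0.001,
    variants = data.frame(chrom = "chr1", pos = 101L, alt = "T", vaf = 0.05),
    seed = 31))
  calls <- callVariants(sim$profiles)
  pass <- calls[calls$filter == "PASS", ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$pos, 101L)
  expect_equal(pass$alt, "T")
  expect_equal(pass$altCount, sim$truth$realizedCount)
  expect_equal(pass$vaf, pass$altCount / pass$depth)
  ## deterministic: identical input, identical calls
  sim2 <- simulateProfiles(simulationConfig(
    regions = simpleRegion(201), depth = 1000, errorRate = 0.001,
    variants = data.frame(chrom = "chr1", pos = 101L, alt = "T", vaf = 0.05),
    seed = 31))
  expect_identical(callVariants(sim2$profiles), calls)
  expect_identical(callVariants(list()), callVariants(list()))
  expect_equal(nrow(callVariants(list())), 0L)
})

test_that("every emitted PASS call is re-verified by the raw-data oracle", {
  sim <- simulateProfiles(simulationConfig(
    regions = simpleRegion(400), depth = 600, errorRate = 0.004,
    variants = data.frame(chrom = "chr1", pos = c(80L, 320L),
                          alt = c("T", "G"), vaf = c(0.03, 0.10)),
    seed = 9))
  prof <- sim$profiles[[1]]
  calls <- callVariants(prof)
  expect_gt(nrow(calls), 0L)
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$filter[i] == "PASS", passOracle(prof, calls[i, ]),
                 info = sprintf("call at %d/%s", calls$pos[i], calls$alt[i]))
  }
})

test_that("pass-only and reporting cutoffs subset the emitted calls", {
  sim <- simulateProfiles(simulationConfig(
    regions = simpleRegion(201), depth = 1000, errorRate = 0.002,
    variants = data.frame(chrom = "chr1", pos = 101L, alt = "T", vaf = 0.02),
    seed = 13))
  all <- callVariants(sim$profiles)
  passOnly <- callVariants(sim$profiles, callerConfig(passOnly = TRUE))
  expect_true(all(passOnly$filter == "PASS"))
  expect_equal(passOnly, all[all$filter == "PASS", ],
               ignore_attr = "row.names")
  cut <- callVariants(sim$profiles, callerConfig(vafMinSnv = 0.01))
  isSub <- !substr(cut$alt, 1, 1) %in% c("+", "-")
  expect_true(all(cut$vaf[isSub] >= 0.01))
})

test_that("the LOD is the direct inversion of the calling criteria", {
  ## noise 0 everywhere at depth 1000: LOD forced to 1/1000 by the
  ## statistical step
  altVec <- rep(0L, 201)
  prof <- parsePileup(mkNoiseLines(altVec, depth = 1000L))[[1]]
  tab <- lodReport(prof, perPosition = TRUE)
  expect_equal(tab$lod, rep(1 / 1000, 201))
  reg <- lodReport(prof)
  expect_equal(reg$lod_mean, 1 / 1000)
  expect_equal(reg$lod_max, 1 / 1000)
  expect_equal(reg$mean_depth, 1000)

  ## noise count 2 at depth 1000: max(2 x 0.002, 3/1000) = 0.004
  altVec <- rep(c(0L, 2L), length.out = 201)
  prof2 <- parsePileup(mkNoiseLines(altVec, depth = 1000L))[[1]]
  one <- lodReport(prof2, positions = data.frame(chrom = "chr1", pos = 101L))
  expect_equal(one$lod, max(2 * 2 / 1000, 3 / 1000))

  ## tenfold depth scales the detection limit down tenfold
  prof3 <- parsePileup(mkNoiseLines(rep(0L, 201), depth = 150L))[[1]]
  prof4 <- parsePileup(mkNoiseLines(rep(0L, 201), depth = 1500L))[[1]]
  expect_equal(lodReport(prof3)$lod_mean / lodReport(prof4)$lod_mean, 10)

  expect_error(lodReport(list(prof),
                         positions = data.frame(chrom = "chr9", pos = 5L)),
               "not covered")
})

test_that("position reports mirror the stored observations", {
  sim <- simulateProfiles(simulationConfig(
    regions = simpleRegion(201), depth = 1000, errorRate = 0,
    variants = data.frame(chrom = "chr1", pos = 101L, alt = "T", vaf = 0.04),
    seed = 3))
  prof <- sim$profiles[[1]]
  rep <- positionReport(prof, "chr1", 101L)
  expect_equal(rep$alt, "T")
  expect_equal(rep$altCount, sim$truth$realizedCount)
  expect_equal(rep$altFwd + rep$altRev, rep$altCount)
  expect_equal(rep$depth, 1000L)
  expect_s4_class(rep$noise, "NoiseEstimate")

  ## all-reference position: no alternative allele reported
  repRef <- positionReport(prof, "chr1", 50L)
  expect_true(is.na(repRef$alt))
  expect_equal(repRef$altCount, 0L)
  expect_gt(repRef$meanQual, 20)

  ## region edge: window clipped, report still produced
  repEdge <- positionReport(prof, "chr1", 1L)
  expect_equal(repEdge$noise@windowStart, 1L)
  expect_error(positionReport(prof, "chr1", 9999L), "not covered")
  expect_error(positionReport(prof, "chrX", 10L), "not covered")
})
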