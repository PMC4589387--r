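emptyLd <- function() LDTable(data.frame(rsid_a = "zz1", rsid_b = "zz2", r2 = 0.9))

test_that("TSS distance is the nearest-site distance, with Inf off the TSS map", {
  tss <- tssRanges(c("chrT", "chrT"), c(100, 300))
  expect_equal(tssDistance(toyVariants(100), tss), 0)
  expect_equal(tssDistance(toyVariants(150), tss), 50)
  expect_equal(tssDistance(toyVariants(201), tss), 99)
  expect_equal(tssDistance(toyVariants(1000, chrom = "chrZ"), tss), Inf)
  expect_error(tssDistance(toyVariants(1), tss[0]), "empty")

  set.seed(41)
  tChrom <- sample(c("chr1", "chr2"), 40, TRUE)
  tPos <- sample.int(1e6, 40)
  tss <- tssRanges(tChrom, tPos)
  vChrom <- sample(c("chr1", "chr2", "chr3"), 1000, TRUE)
  vPos <- sample.int(1e6, 1000, replace = TRUE)
  v <- variantRanges(sprintf("rs%04d", 1:1000), vChrom, vPos)
  expect_equal(tssDistance(v, tss),
               oracleTssDistance(normalizeChrom(vChrom), vPos,
                                 as.character(GenomicRanges::seqnames(tss)),
                                 GenomicRanges::start(tss)))
})

test_that("bin scheme edges are input quartiles and counts partition the input", {
  # 8 SNPs with distinct distances; no LD -> partner counts all zero
  tss <- tssRanges("chrT", 1)
  v <- toyVariants(c(11, 21, 31, 41, 51, 61, 71, 81))
  scheme <- buildBinScheme(v, tss, emptyLd())
  expect_equal(sum(scheme@inputCounts), 8L)
  # distances 10..80: quartile edges separate 2 SNPs per margin
  expect_equal(unname(colSums(matrix(scheme@inputCounts, 4, byrow = FALSE)) > 0),
               c(TRUE, FALSE, FALSE, FALSE))  # all in ld bin 0
  expect_equal(unname(rowSums(scheme@inputCounts)), c(2L, 2L, 2L, 2L))

  # degenerate: all SNPs identical on both axes -> one cell holds everything
  scheme <- buildBinScheme(toyVariants(rep(50, 6), rsid = sprintf("d%d", 1:6)),
                           tss, emptyLd())
  expect_equal(sum(scheme@inputCounts == 6L), 1L)
  expect_equal(sum(scheme@inputCounts), 6L)

  expect_error(buildBinScheme(toyVariants(c(1, 2, 3)), tss, emptyLd()),
               "at least 4")
})

test_that("bin assignment sends edge ties to the lower bin and is self-consistent", {
  tss <- tssRanges("chrT", 1)
  v <- toyVariants(c(11, 21, 31, 41, 51, 61, 71, 81))
  scheme <- buildBinScheme(v, tss, emptyLd())
  b <- assignBin(toyVariants(2, rsid = "low"), scheme, tss, emptyLd())
  expect_equal(unname(b[1, "tss_bin"]), 0L)   # below the first edge
  med <- scheme@tssEdges[2]
  b <- assignBin(toyVariants(med + 1, rsid = "atmed"), scheme, tss, emptyLd())
  expect_equal(unname(b[1, "tss_bin"]), 1L)   # equal to the median edge: lower bin
  # re-assigning the input reproduces inputCounts
  bins <- assignBin(v, scheme, tss, emptyLd())
  counts <- table(factor(bins[, 1], 0:3), factor(bins[, 2], 0:3))
  expect_equal(unclass(unname(counts)), unclass(unname(scheme@inputCounts)),
               ignore_attr = TRUE)
})

test_that("matched sets conserve bin counts exactly and are seed-deterministic", {
  st <- generateStudy(syntheticConfig(seed = 3, nPlatform = 1500,
                                      nInput = 12, nTss = 60))
  scheme <- buildBinScheme(st@input, st@tss, st@ld)
  ms <- sampleMatchedSets(st@platform, scheme, st@tss, st@ld,
                          nSets = 40, seed = 99)
  expect_equal(numSets(ms), 40L)
  platBins <- assignBin(st@platform, scheme, st@tss, st@ld)
  platId <- platBins[, 1] * 4L + platBins[, 2] + 1L
  need <- as.integer(t(scheme@inputCounts))
  for (s in seq_len(numSets(ms))) {
    idx <- ms@sets[s, ]
    expect_false(anyDuplicated(idx) > 0)  # without replacement within a set
    expect_equal(tabulate(platId[idx], 16L), need)  # exact bin conservation
  }
  ms2 <- sampleMatchedSets(st@platform, scheme, st@tss, st@ld,
                           nSets = 40, seed = 99)
  expect_identical(ms@sets, ms2@sets)
  ms3 <- sampleMatchedSets(st@platform, scheme, st@tss, st@ld,
                           nSets = 40, seed = 100)
  expect_false(identical(ms@sets, ms3@sets))
})

test_that("a bin whose platform supply equals the demand is drawn in full", {
  tss <- tssRanges("chrT", 1)
  # 4 input SNPs, all in one cell (identical statistics)
  input <- toyVariants(rep(500, 4), rsid = sprintf("i%d", 1:4))
  scheme <- buildBinScheme(input, tss, emptyLd())
  # platform with exactly 4 SNPs in that cell
  platform <- toyVariants(rep(500, 4), rsid = sprintf("p%d", 1:4))
  ms <- sampleMatchedSets(platform, scheme, tss, emptyLd(), nSets = 5, seed = 1)
  for (s in 1:5) expect_setequal(setMembers(ms, s), sprintf("p%d", 1:4))
})

test_that("an undersupplied bin aborts with the bin and its deficit", {
  tss <- tssRanges("chrT", 1)
  input <- toyVariants(rep(500, 5), rsid = sprintf("i%d", 1:5))
  scheme <- buildBinScheme(input, tss, emptyLd())
  platform <- toyVariants(rep(500, 3), rsid = sprintf("p%d", 1:3))
  expect_error(
    sampleMatchedSets(platform, scheme, tss, emptyLd(), nSets = 2, seed = 1),
    "undersupplied.*deficit 2")
})
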