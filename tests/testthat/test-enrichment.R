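test_that("LD expansion builds one locus per index SNP, index included first", {
  ld <- LDTable(data.frame(rsid_a = c("x", "x"), rsid_b = c("y", "z"),
                           r2 = c(0.85, 0.5)))
  loci <- expandToLoci(c("x", "lonely"), ld, 0.8)
  expect_identical(loci$x, c("x", "y"))
  expect_identical(loci$lonely, "lonely")

  set.seed(61)
  rs <- sprintf("rs%02d", 1:15)
  pairs <- expand.grid(rsid_a = rs, rsid_b = rs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$rsid_a < pairs$rsid_b, ]
  pairs <- pairs[sample.int(nrow(pairs), 40), ]
  pairs$r2 <- runif(40)
  ld <- LDTable(pairs)
  loci <- expandToLoci(rs, ld, 0.6)
  for (v in rs) {
    expect_setequal(loci[[v]], c(v, oraclePartners(pairs, v, 0.6)))
  }
})

test_that("locus overlap counting detects partner-only hits and collapses shared LD", {
  track <- toyTrack("chrT", 100, 200)
  catalog <- variantRanges(c("idx", "tag", "far", "idx2"), "chrT",
                           c(5000, 150, 9000, 6000))
  # index inside the interval
  expect_equal(countOverlappingLoci(list(a = "tag"), track, catalog), 1L)
  # index misses, its tag hits: the locus still counts (tag-SNP situation)
  expect_equal(countOverlappingLoci(list(a = c("idx", "tag")), track, catalog), 1L)
  # two hitting loci sharing the tag collapse to one
  expect_equal(countOverlappingLoci(
    list(a = c("idx", "tag"), b = c("idx2", "tag")), track, catalog), 1L)
  # disjoint hitting loci stay separate
  catalog2 <- variantRanges(c("i1", "i2"), "chrT", c(150, 180))
  expect_equal(countOverlappingLoci(list(a = "i1", b = "i2"), track, catalog2), 2L)
  # non-hitting loci never merge anything
  expect_equal(countOverlappingLoci(list(a = "far"), track, catalog), 0L)
})

test_that("unresolvable locus members error by default, drop when permissive", {
  track <- toyTrack("chrT", 100, 200)
  catalog <- variantRanges("idx", "chrT", 150)
  expect_error(countOverlappingLoci(list(a = c("idx", "ghost")), track, catalog),
               "ghost")
  expect_warning(
    n <- countOverlappingLoci(list(a = c("idx", "ghost")), track, catalog,
                              permissive = TRUE),
    "dropping")
  expect_equal(n, 1L)
})

test_that("collapse counting matches the brute-force component oracle", {
  set.seed(71)
  for (rep in 1:40) {
    L <- 300L
    toy <- randomToyTrack(L, nIntervals = 6L, maxLen = 30L)
    nSnp <- 12L
    pos <- sample.int(L, nSnp)
    rs <- sprintf("s%02d", seq_len(nSnp))
    catalog <- variantRanges(rs, "chrT", pos)
    nLoci <- 5L
    loci <- lapply(seq_len(nLoci), function(i)
      unique(c(rs[i], sample(rs, sample.int(3L, 1L)))))
    names(loci) <- rs[seq_len(nLoci)]
    member <- oracleMembership(L, toy$start0, toy$end0)
    hit <- vapply(loci, function(m) any(member[pos[match(m, rs)]]), TRUE)
    expect_equal(countOverlappingLoci(loci, toy$track, catalog),
                 oracleComponents(loci[hit]))
  }
})

test_that("empirical p is the exceedance fraction, bounded below by 1/n", {
  nulls <- c(rep(0L, 9998L), 12L, 13L)
  ep <- empiricalP(12L, nulls)
  expect_equal(ep$pValue, 0.0002)
  expect_false(ep$pIsBound)
  expect_equal(formatPValue(ep), "0.0002")

  ep <- empiricalP(20L, nulls)
  expect_true(ep$pIsBound)
  expect_equal(ep$pValue, 1e-4)
  expect_equal(formatPValue(ep), "< 0.0001")

  expect_equal(empiricalP(5L, rep(5L, 100L))$pValue, 1)
  expect_error(empiricalP(1L, integer()), "empty")
})

test_that("Bonferroni threshold scales the alpha by the track count", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 125), 4e-4)
  expect_equal(bonferroniThreshold(0.05, 10), 0.005)
  expect_error(bonferroniThreshold(0.05, 0), ">= 1")
})

test_that("saturating and empty tracks give the degenerate run results", {
  # LD-free platform so every locus is a singleton and cannot collapse
  set.seed(12)
  platform <- variantRanges(sprintf("p%03d", 1:400),
                            sample(c("chr1", "chr2"), 400, TRUE),
                            sample.int(1e7, 400), runif(400, 0.05, 0.5))
  input <- platform[sample.int(400, 10)]
  S4Vectors::mcols(input)$gwas_p <- 1e-8
  tss <- tssRanges(c("chr1", "chr2"), c(5e6, 5e6))
  ld <- LDTable(data.frame(rsid_a = "zz1", rsid_b = "zz2", r2 = 0.9))
  whole <- toyTrack(c("chr1", "chr2"), c(1, 1), c(1e7, 1e7), name = "whole")
  empty <- GenomicRanges::GRanges()
  run <- runEnrichment(input, platform, list(whole = whole, empty = empty),
                       tss, ld, nSets = 50, seed = 4)
  w <- run@results$whole
  expect_equal(w@observed, 10L)                   # observed = number of loci
  expect_true(all(w@nullCounts == 10L))           # every null saturates alike
  expect_equal(w@pValue, 1)
  e <- run@results$empty
  expect_equal(e@observed, 0L)
  expect_equal(e@pValue, 1)
})

test_that("nested tracks give monotone counts against shared null sets", {
  st <- generateStudy(syntheticConfig(seed = 13, nPlatform = 1200,
                                      nInput = 10, nTss = 50))
  big <- st@tracks[[1]]
  small <- big[seq_len(floor(length(big) / 3))]
  run <- runEnrichment(st@input, st@platform, list(small = small, big = big),
                       st@tss, st@ld, nSets = 80, seed = 6)
  expect_lte(run@results$small@observed, run@results$big@observed)
  expect_true(all(run@results$small@nullCounts <= run@results$big@nullCounts))
  # identical track twice in one run -> byte-identical null counts
  run2 <- runEnrichment(st@input, st@platform, list(a = big, b = big),
                        st@tss, st@ld, nSets = 80, seed = 6)
  expect_identical(run2@results$a@nullCounts, run2@results$b@nullCounts)
})

test_that("results tabulate in the supplementary-table layout", {
  st <- generateStudy(syntheticConfig(seed = 14, nPlatform = 1200,
                                      nInput = 8, nTss = 50))
  run <- runEnrichment(st@input, st@platform, st@tracks, st@tss, st@ld,
                       nSets = 30, seed = 2)
  tab <- resultsTable(run)
  expect_named(tab, c("track", "OrigLoci", "RandGeOrig", "Random_Avg",
                      "pValue", "r2_threshold", "n_sets", "seed"))
  expect_equal(tab$n_sets, 30L)
  h <- nullHistogram(run@results[[1]])
  expect_equal(sum(h$frequency), 30L)
})
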