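toyLd <- function() {
  LDTable(data.frame(rsid_a = c("x", "x"), rsid_b = c("y", "z"),
                     r2 = c(0.85, 0.5)))
}

test_that("partner queries apply the threshold comparator of the r2 ladder", {
  ld <- toyLd()
  expect_setequal(ldPartners(ld, "x", 0.8), "y")
  expect_setequal(ldPartners(ld, "x", 0.4), c("y", "z"))
  expect_identical(ldPartners(ld, "nosuch", 0.2), character(0))
  # strict comparator below 1: a pair at exactly the threshold is excluded
  ld2 <- LDTable(data.frame(rsid_a = "a", rsid_b = "b", r2 = 0.8))
  expect_identical(ldPartners(ld2, "a", 0.8), character(0))
  # equality at the top of the ladder
  ld3 <- LDTable(data.frame(rsid_a = c("a", "a"), rsid_b = c("b", "c"),
                            r2 = c(1, 0.999)))
  expect_setequal(ldPartners(ld3, "a", 1), "b")
  # the classic tag-SNP situation: r2 = 0.978 qualifies at the 0.8 cutoff
  ld4 <- LDTable(data.frame(rsid_a = "rs7097", rsid_b = "rs694609",
                            r2 = 0.978, dprime = 0.996))
  expect_setequal(ldPartners(ld4, "rs7097", 0.8), "rs694609")
})

test_that("partner counts match the direct-filter oracle and are monotone", {
  ld <- toyLd()
  expect_identical(ldPartnerCount(ld, "x", 0.4), 2L)
  expect_identical(ldPartnerCount(ld, "x", 0.8), 1L)
  expect_identical(ldPartnerCount(ld, "unknown", 0.2), 0L)

  set.seed(21)
  rs <- sprintf("rs%02d", 1:12)
  pairs <- expand.grid(rsid_a = rs, rsid_b = rs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$rsid_a < pairs$rsid_b, ]
  pairs <- pairs[sample.int(nrow(pairs), 30L), ]
  pairs$r2 <- round(runif(30), 3)
  ld <- LDTable(pairs)
  for (t in c(0.2, 0.4, 0.6, 0.8, 1)) {
    for (v in rs) {
      expect_setequal(ldPartners(ld, v, t), oraclePartners(pairs, v, t))
    }
  }
  for (v in rs) {
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
                     function(t) ldPartnerCount(ld, v, t), integer(1L))
    expect_true(all(diff(counts) <= 0L))  # non-increasing in threshold
  }
})

test_that("partner storage is symmetric", {
  set.seed(33)
  rs <- sprintf("rs%02d", 1:10)
  pairs <- data.frame(rsid_a = sample(rs, 20, TRUE),
                      rsid_b = sample(rs, 20, TRUE), r2 = runif(20))
  pairs <- pairs[pairs$rsid_a != pairs$rsid_b, ]
  pairs <- pairs[!duplicated(paste(pmin(pairs$rsid_a, pairs$rsid_b),
                                   pmax(pairs$rsid_a, pairs$rsid_b))), ]
  ld <- LDTable(pairs)
  for (a in rs) {
    for (b in ldPartners(ld, a, 0.2)) {
      expect_true(a %in% ldPartners(ld, b, 0.2))
    }
  }
})

test_that("LDTable rejects self-pairs, bad r2 and conflicting duplicates", {
  expect_error(LDTable(data.frame(rsid_a = "a", rsid_b = "a", r2 = 0.5)),
               "self-pairs")
  expect_error(LDTable(data.frame(rsid_a = "a", rsid_b = "b", r2 = 1.2)),
               "r2")
  expect_error(LDTable(data.frame(rsid_a = c("a", "b"), rsid_b = c("b", "a"),
                                  r2 = c(0.5, 0.7))), "conflicting")
  # identical duplicates collapse silently
  ld <- LDTable(data.frame(rsid_a = c("a", "b"), rsid_b = c("b", "a"),
                           r2 = c(0.5, 0.5)))
  expect_identical(ldPartnerCount(ld, "a", 0.4), 1L)
})

test_that("independence pruning keeps the most significant member of each clump", {
  mkv <- function(p) variantRanges(c("a", "b", "c"), "chr1",
                                   c(1e6, 2e6, 3e6), 0.2, p)
  # no correlated pair: unchanged
  ldNone <- LDTable(data.frame(rsid_a = "a", rsid_b = "b", r2 = 0.1))
  v <- mkv(c(1e-9, 1e-6, 1e-7))
  expect_identical(variantRsid(independencePrune(v, ldNone)), c("a", "b", "c"))

  # correlated pair keeps the lower p-value
  ldPair <- LDTable(data.frame(rsid_a = "a", rsid_b = "b", r2 = 0.9))
  expect_identical(variantRsid(independencePrune(v, ldPair)), c("a", "c"))

  # chain a-b, b-c above threshold, a-c below: greedy by ascending p -> {a, c}
  ldChain <- LDTable(data.frame(rsid_a = c("a", "b", "a"),
                                rsid_b = c("b", "c", "c"),
                                r2 = c(0.9, 0.9, 0.1)))
  v <- mkv(c(1e-9, 1e-8, 1e-7))
  kept <- variantRsid(independencePrune(v, ldChain))
  expect_identical(kept, c("a", "c"))

  # survivors are pairwise independent and the result is maximal:
  # re-adding the removed SNP recreates a correlated pair
  removed <- setdiff(c("a", "b", "c"), kept)
  expect_true(all(vapply(removed, function(r)
    length(intersect(ldPartners(ldChain, r, 0.8), kept)) > 0, TRUE)))

  # gwas_p required on correlated variants
  v2 <- variantRanges(c("a", "b"), "chr1", c(1, 2), 0.2, c(1e-8, NA))
  expect_error(independencePrune(v2, ldPair), "gwas_p")
  # but not on uncorrelated ones
  v3 <- variantRanges(c("a", "q"), "chr1", c(1, 2), 0.2, c(1e-8, NA))
  expect_silent(independencePrune(v3, ldPair))

  # p-value tie resolves to the lexicographically smaller rsid
  v4 <- variantRanges(c("b", "a"), "chr1", c(1, 2), 0.2, c(1e-8, 1e-8))
  expect_identical(variantRsid(independencePrune(v4, ldPair)), "a")
})
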