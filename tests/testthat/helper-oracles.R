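# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval/graph machinery: membership is evaluated
# per base, components by repeated pairwise merging.

# per-base membership vector of raw BED-style intervals (0-based half-open)
# on a single toy chromosome of length L
oracleMembership <- function(L, start0, end0) {
  covered <- logical(L)
  for (i in seq_along(start0)) {
    lo <- start0[i] + 1L
    hi <- min(end0[i], L)
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  covered
}

# connected-component count over member sets: merge any two intersecting
# sets until a fixpoint is reached
oracleComponents <- function(memberSets) {
  sets <- memberSets
  repeat {
    merged <- FALSE
    n <- length(sets)
    if (n <= 1L) break
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  length(sets)
}

# direct filter over a pair data.frame (columns rsid_a, rsid_b, r2)
oraclePartners <- function(pairs, rsid, r2Min) {
  keep <- if (r2Min >= 1) pairs$r2 >= 1 - 1e-9 else pairs$r2 > r2Min
  sort(unique(c(pairs$rsid_b[keep & pairs$rsid_a == rsid],
                pairs$rsid_a[keep & pairs$rsid_b == rsid])))
}

# nearest-TSS distance by full scan
oracleTssDistance <- function(vChrom, vPos, tChrom, tPos) {
  vapply(seq_along(vPos), function(i) {
    d <- abs(tPos[tChrom == vChrom[i]] - vPos[i])
    if (length(d)) min(d) else Inf
  }, numeric(1))
}

# small random toy track on one chromosome, returned with its raw intervals
randomToyTrack <- function(L, nIntervals, maxLen = 40L) {
  s <- sample.int(L - 1L, nIntervals, replace = TRUE) - 1L
  e <- pmin(s + sample.int(maxLen, nIntervals, replace = TRUE), L)
  ok <- s < e
  f <- tempfile(fileext = ".bed")
  writeLines(sprintf("chrT\t%d\t%d", s[ok], e[ok]), f)
  list(track = readBed(f), start0 = s[ok], end0 = e[ok], path = f)
}

toyVariants <- function(pos, chrom = "chrT", rsid = sprintf("rs%03d", seq_along(pos)),
                        maf = 0.2, gwasP = NA_real_) {
  variantRanges(rsid, chrom, pos, maf, gwasP)
}

toyTrack <- function(chrom, start1, end1, name = "toy") {
  normalizeTrack(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = start1, end = end1)), name = name)
}
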