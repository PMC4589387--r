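# sentinel used in place of Inf when a chromosome has no TSS: larger than
# any real genomic distance, finite so quartile interpolation stays defined
.TSS_SENTINEL <- 1e15

#' Distance to the nearest transcription start site
#'
#' For each variant, the minimum |pos - site| over TSS sites on the same
#' chromosome. Variants on a chromosome with no TSS get `Inf`; the bin
#' scheme places them in the top distance bin.
#'
#' @param variants variant GRanges.
#' @param tss non-empty TSS GRanges (see [readTss()]).
#' @return numeric vector of distances in bp (`Inf` where no site exists).
#' @export
tssDistance <- function(variants, tss) {
  if (!length(tss)) stop("the TSS list is empty")
  vChrom <- as.character(GenomicRanges::seqnames(variants))
  vPos <- GenomicRanges::start(variants)
  tChrom <- as.character(GenomicRanges::seqnames(tss))
  tPos <- GenomicRanges::start(tss)
  out <- rep(Inf, length(variants))
  for (ch in unique(vChrom)) {
    tp <- sort(tPos[tChrom == ch])
    if (!length(tp)) next
    vi <- which(vChrom == ch)
    vp <- vPos[vi]
    k <- findInterval(vp, tp)
    dLeft <- ifelse(k >= 1L, vp - tp[pmax(k, 1L)], Inf)
    dRight <- ifelse(k < length(tp), tp[pmin(k + 1L, length(tp))] - vp, Inf)
    out[vi] <- pmin(dLeft, dRight)
  }
  out
}

# bin index 0..3: number of edges strictly below the value (ties fall low)
.binIndex <- function(x, edges) {
  x <- pmin(x, .TSS_SENTINEL)
  findInterval(x, edges, left.open = TRUE)
}

# joint bin id 1..16 from the two 0-based margins
.binId <- function(tssBin, ldBin) tssBin * 4L + ldBin + 1L

.binLabel <- function(id) {
  id <- id - 1L
  sprintf("tss_q%d/ld_q%d", id %/% 4L + 1L, id %% 4L + 1L)
}

#' Build the quartile bin scheme from the input SNPs
#'
#' Computes the input SNPs' distances to the nearest TSS and LD-partner
#' counts, takes the 25th/50th/75th percentiles of each (type-7 linear
#' interpolation) as bin edges, and tabulates the input SNPs over the
#' resulting 4 x 4 grid. Matched random sets reproduce this table exactly.
#'
#' @param input variant GRanges with at least 4 SNPs.
#' @param tss TSS GRanges.
#' @param ld an [LDTable-class].
#' @param r2Min LD threshold for partner counts, default 0.8.
#' @return a [BinScheme-class].
#' @export
buildBinScheme <- function(input, tss, ld, r2Min = 0.8) {
  if (length(input) < 4L)
    stop("at least 4 input SNPs are needed to define quartile bins")
  d <- pmin(tssDistance(input, tss), .TSS_SENTINEL)
  k <- ldPartnerCount(ld, variantRsid(input), r2Min)
  tssEdges <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  ldEdges <- stats::quantile(as.numeric(k), c(0.25, 0.5, 0.75),
                             names = FALSE, type = 7)
  id <- .binId(.binIndex(d, tssEdges), .binIndex(k, ldEdges))
  counts <- matrix(tabulate(id, nbins = 16L), nrow = 4L, byrow = TRUE,
                   dimnames = list(paste0("tss_q", 1:4), paste0("ld_q", 1:4)))
  storage.mode(counts) <- "integer"
  new("BinScheme", tssEdges = tssEdges, ldEdges = ldEdges,
      inputCounts = counts, r2Threshold = r2Min)
}

#' Assign variants to bins of a scheme
#'
#' Compares each variant's TSS distance and LD-partner count to the
#' scheme's edges; a value equal to an edge falls into the lower bin, so
#' assignment is total and deterministic. Variants on chromosomes with no
#' TSS fall into the top distance bin.
#'
#' @param variants variant GRanges.
#' @param scheme a [BinScheme-class].
#' @param tss TSS GRanges.
#' @param ld an [LDTable-class].
#' @param r2Min LD threshold; defaults to the scheme's.
#' @return integer matrix with columns `tss_bin` and `ld_bin` (0-based).
#' @export
assignBin <- function(variants, scheme, tss, ld, r2Min = scheme@r2Threshold) {
  d <- tssDistance(variants, tss)
  k <- ldPartnerCount(ld, variantRsid(variants), r2Min)
  cbind(tss_bin = .binIndex(d, scheme@tssEdges),
        ld_bin = .binIndex(as.numeric(k), scheme@ldEdges))
}

#' Draw matched random SNP sets from the platform
#'
#' Bins the (already curated) platform catalog under the input-derived
#' scheme and draws `nSets` random sets, each reproducing the input's
#' per-bin counts exactly. Sampling is without replacement within a set
#' and independent across sets. Each set uses its own RNG substream
#' derived from the master seed, so results are reproducible and
#' independent of generation order.
#'
#' @param platform curated platform variant GRanges (HLA-excluded,
#'   duplicate-position-dropped, MAF-filtered).
#' @param scheme a [BinScheme-class].
#' @param tss TSS GRanges.
#' @param ld an [LDTable-class].
#' @param nSets number of random sets.
#' @param seed master RNG seed.
#' @param r2Min LD threshold; defaults to the scheme's.
#' @return a [MatchedSets-class].
#' @export
sampleMatchedSets <- function(platform, scheme, tss, ld, nSets, seed,
                              r2Min = scheme@r2Threshold) {
  nSets <- as.integer(nSets)
  seed <- as.integer(seed)
  bins <- assignBin(platform, scheme, tss, ld, r2Min)
  id <- .binId(bins[, 1L], bins[, 2L])
  supply <- split(seq_along(id), factor(id, levels = 1:16))
  need <- as.integer(t(scheme@inputCounts))  # row-major: binId order
  have <- lengths(supply)
  short <- which(need > have)
  if (length(short))
    stop(sprintf(
      "platform bin %s undersupplied: need %d matched SNPs, have %d (deficit %d)",
      .binLabel(short[1L]), need[short[1L]], have[short[1L]],
      need[short[1L]] - have[short[1L]]))
  activeBins <- which(need > 0L)
  columnBin <- rep.int(activeBins, need[activeBins])
  nMembers <- length(columnBin)
  sets <- matrix(0L, nrow = nSets, ncol = nMembers)
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(seed)
  subSeeds <- sample.int(2147483646L, nSets)
  for (s in seq_len(nSets)) {
    set.seed(subSeeds[s])
    sets[s, ] <- unlist(lapply(activeBins, function(b) {
      pool <- supply[[b]]
      pool[sample.int(length(pool), need[b])]
    }), use.names = FALSE)
  }
  new("MatchedSets", sets = sets, columnBin = columnBin,
      platformRsid = variantRsid(platform), seed = seed)
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @rdname sampleMatchedSets
#' @param x a [MatchedSets-class].
#' @export
numSets <- function(x) nrow(x@sets)

#' Member rsIDs of one matched set
#'
#' @param x a [MatchedSets-class].
#' @param i set index (1-based).
#' @return character vector of member rsIDs.
#' @export
setMembers <- function(x, i) x@platformRsid[x@sets[i, ]]
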