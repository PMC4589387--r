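#' The HLA exclusion region
#'
#' The extended HLA region on build 37, chr6:29,570,005-33,377,658,
#' excluded by default from both the input SNP list and the platform
#' sampling frame because of its extreme variability and LD.
#'
#' @return a width-1-chromosome GRanges covering the region (1-based
#'   inclusive bounds).
#' @export
hlaRegion <- function() {
  GenomicRanges::GRanges("chr6", IRanges::IRanges(start = 29570005L,
                                                  end = 33377658L))
}

#' Remove variants inside a genomic region
#'
#' Drops every variant whose position falls within the region (1-based
#' inclusive on the region's chromosome); order is preserved.
#'
#' @param variants variant GRanges.
#' @param region a GRanges region; defaults to [hlaRegion()].
#' @return the surviving subset, in input order.
#' @export
excludeRegion <- function(variants, region = hlaRegion()) {
  variants[!.overlapsAnyQuiet(variants, region)]
}

#' Prune variants closer than a minimum separation
#'
#' Greedy by ascending GWAS p-value (ties broken by rsID): each kept
#' variant removes all yet-unkept variants on the same chromosome at
#' distance strictly less than `minSeparation` base pairs. Two variants
#' exactly `minSeparation` apart are both kept. Input order is preserved.
#'
#' @param variants variant GRanges; `gwas_p` is required on any variant
#'   within `minSeparation` of another.
#' @param minSeparation minimum separation in bp, default 1 Mb.
#' @return the surviving subset, in input order.
#' @export
locationPrune <- function(variants, minSeparation = 1e6) {
  n <- length(variants)
  if (n <= 1L) return(variants)
  chrom <- as.character(GenomicRanges::seqnames(variants))
  pos <- GenomicRanges::start(variants)
  rsid <- variantRsid(variants)
  p <- S4Vectors::mcols(variants)$gwas_p
  near <- lapply(seq_len(n), function(i) {
    j <- which(chrom == chrom[i] & abs(pos - pos[i]) < minSeparation)
    j[j != i]
  })
  involved <- lengths(near) > 0L
  if (any(involved & is.na(p)))
    stop("gwas_p required for proximal variant(s): ",
         paste(rsid[involved & is.na(p)], collapse = ", "))
  ord <- order(ifelse(is.na(p), Inf, p), rsid)
  keep <- logical(n)
  removed <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    keep[i] <- TRUE
    removed[near[[i]]] <- TRUE
  }
  variants[keep]
}

#' Drop all variants at duplicated start positions
#'
#' Every (chrom, pos) shared by two or more variants is removed entirely
#' (no representative is kept); variants at unique positions pass through
#' in order. Applied to the platform catalog so that the LD table never
#' has to disambiguate co-located records.
#'
#' @param variants variant GRanges.
#' @return the surviving subset, in input order.
#' @export
dropDuplicatePositions <- function(variants) {
  key <- paste(as.character(GenomicRanges::seqnames(variants)),
               GenomicRanges::start(variants))
  counts <- table(key)
  variants[counts[key] == 1L]
}

#' Filter variants by minor allele frequency
#'
#' Keeps variants with `maf >= minMaf` (the boundary value is kept).
#' A missing MAF is an error, matching the platform catalog contract.
#'
#' @param variants variant GRanges with `maf` on every variant.
#' @param minMaf inclusive lower bound, default 0.05.
#' @return the surviving subset, in input order.
#' @export
mafFilter <- function(variants, minMaf = 0.05) {
  maf <- S4Vectors::mcols(variants)$maf
  if (any(is.na(maf)))
    stop("maf missing for: ",
         paste(variantRsid(variants)[is.na(maf)], collapse = ", "))
  variants[maf >= minMaf]
}

#' Summary statistics of a variant set's MAF distribution
#'
#' Mean plus the five-number summary, used to report that matched random
#' sets resemble the input SNPs in allele frequency.
#'
#' @param variants non-empty variant GRanges with `maf`.
#' @return named numeric: `mean`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
mafDiagnostics <- function(variants) {
  if (!length(variants)) stop("cannot summarise an empty variant set")
  maf <- S4Vectors::mcols(variants)$maf
  if (any(is.na(maf)))
    stop("maf missing for: ",
         paste(variantRsid(variants)[is.na(maf)], collapse = ", "))
  q <- stats::quantile(maf, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(mean = mean(maf), min = q[1L], q1 = q[2L],
    median = q[3L], q3 = q[4L], max = q[5L])
}
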