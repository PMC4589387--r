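#' Define a locus for the circular annotation-shift test
#'
#' Locus bounds run from the most upstream to the most downstream member
#' (the index SNP counts as a member of its own locus), extended on each
#' side by twice the median interval length of the tested annotation and
#' clipped at the chromosome start. The locus is later treated as a
#' circle of `end - start + 1` bases.
#'
#' @param members width-1 GRanges of the locus members (index SNP plus LD
#'   partners), all on one chromosome, with mcols `rsid`.
#' @param track non-empty annotation GRanges (defines the median size).
#' @return a [ShiftLocus-class].
#' @export
defineShiftLocus <- function(members, track) {
  if (!length(members)) stop("a shift locus needs at least one member")
  if (!length(track)) stop("cannot size locus flanks from an empty track")
  chrom <- unique(as.character(GenomicRanges::seqnames(members)))
  if (length(chrom) != 1L)
    stop("locus members must lie on a single chromosome")
  ext <- as.integer(round(2 * stats::median(GenomicRanges::width(track))))
  pos <- GenomicRanges::start(members)
  rsid <- S4Vectors::mcols(members)$rsid
  if (is.null(rsid)) rsid <- paste0("member", seq_along(members))
  new("ShiftLocus",
      chrom = chrom,
      memberRsid = as.character(rsid),
      memberPos = as.integer(pos),
      start = max(1L, min(pos) - ext),
      end = max(pos) + ext)
}

#' @rdname defineShiftLocus
#' @param x a [ShiftLocus-class].
#' @export
circumference <- function(x) x@end - x@start + 1L

# annotation intervals clipped to the locus, in 1-based coordinates
# relative to the locus start (1 .. L); returns NULL when none remain
.relativeIntervals <- function(locus, track) {
  onChrom <- track[as.character(GenomicRanges::seqnames(track)) == locus@chrom]
  if (!length(onChrom)) return(NULL)
  s <- pmax(GenomicRanges::start(onChrom), locus@start)
  e <- pmin(GenomicRanges::end(onChrom), locus@end)
  keep <- s <= e
  if (!any(keep)) return(NULL)
  list(start = s[keep] - locus@start + 1L, end = e[keep] - locus@start + 1L)
}

# membership of positions (1..L) in sorted non-overlapping intervals
.inIntervals <- function(pos, rel) {
  k <- findInterval(pos, rel$start)
  k > 0L & pos <= rel$end[pmax(k, 1L)]
}

#' Overlap state of a locus under one circular shift
#'
#' Annotations restricted to the locus are translated by `offset` with
#' wrap-around inside the circularized locus; returns whether any member
#' position then falls inside a shifted interval. Shifting the annotation
#' forward by `offset` is evaluated as shifting the members backward.
#'
#' @param locus a [ShiftLocus-class].
#' @param track annotation GRanges.
#' @param offset integer shift in bp, `0 <= offset < circumference(locus)`.
#' @return logical; `offset = 0` reproduces the unshifted overlap state.
#' @export
circularShiftOverlap <- function(locus, track, offset) {
  L <- circumference(locus)
  if (offset < 0L || offset >= L)
    stop("offset must satisfy 0 <= offset < circumference")
  rel <- .relativeIntervals(locus, track)
  if (is.null(rel)) return(FALSE)
  r <- locus@memberPos - locus@start + 1L
  m <- ((r - 1L - offset) %% L) + 1L
  any(.inIntervals(m, rel))
}

#' Circular annotation-shift enrichment test
#'
#' The locus-local null: in each iteration every locus independently
#' draws a uniform integer offset in `[0, circumference)`, its clipped
#' annotations are rotated by that offset, and the number of loci with
#' any member inside a shifted annotation is recorded. The p-value is the
#' fraction of iterations whose count reaches the observed (unshifted)
#' count; local annotation density within each locus is preserved by
#' construction.
#'
#' @param loci list of [ShiftLocus-class] objects.
#' @param track annotation GRanges.
#' @param iterations number of shift iterations, default 10000.
#' @param seed RNG seed.
#' @param comparator `"geq"` (count >= observed, default) or `"greater"`
#'   (strict).
#' @return a [ShiftResult-class].
#' @export
shiftTest <- function(loci, track, iterations = 10000, seed = 1,
                      comparator = c("geq", "greater")) {
  comparator <- match.arg(comparator)
  iterations <- as.integer(iterations)
  seed <- as.integer(seed)
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(seed)
  counts <- integer(iterations)
  observed <- 0L
  for (locus in loci) {
    L <- circumference(locus)
    rel <- .relativeIntervals(locus, track)
    r <- locus@memberPos - locus@start + 1L
    if (is.null(rel)) next
    if (any(.inIntervals(r, rel))) observed <- observed + 1L
    offsets <- sample.int(L, iterations, replace = TRUE) - 1L
    hit <- rep(FALSE, iterations)
    for (ri in r) {
      m <- ((ri - 1L - offsets) %% L) + 1L
      hit <- hit | .inIntervals(m, rel)
    }
    counts <- counts + hit
  }
  exceed <- if (comparator == "geq") sum(counts >= observed)
            else sum(counts > observed)
  new("ShiftResult",
      observed = observed,
      iterationCounts = counts,
      pValue = exceed / iterations,
      iterations = iterations,
      seed = seed,
      comparator = comparator)
}

#' Build shift loci for a set of index SNPs
#'
#' Convenience wrapper: expands each index SNP to its LD members at
#' `r2Min`, resolves member positions against the catalog and defines one
#' [ShiftLocus-class] per index SNP.
#'
#' @param indexRsids character vector of index SNP rsIDs.
#' @param ld an [LDTable-class].
#' @param catalog variant GRanges resolving rsIDs to positions.
#' @param track annotation GRanges (sizes the locus flanks).
#' @param r2Min LD threshold, default 0.8.
#' @param permissive drop unresolvable members instead of erroring.
#' @return list of [ShiftLocus-class].
#' @export
buildShiftLoci <- function(indexRsids, ld, catalog, track, r2Min = 0.8,
                           permissive = FALSE) {
  loci <- expandToLoci(indexRsids, ld, r2Min)
  catRsid <- variantRsid(catalog)
  lapply(loci, function(mem) {
    idx <- match(mem, catRsid)
    if (anyNA(idx)) {
      if (!permissive)
        stop("member rsID(s) not resolvable to a position: ",
             paste(mem[is.na(idx)], collapse = ", "))
      idx <- idx[!is.na(idx)]
    }
    defineShiftLocus(catalog[idx], track)
  })
}
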