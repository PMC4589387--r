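#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

#' Pairwise linkage-disequilibrium table
#'
#' Holds precomputed pairwise r-squared (and optionally D') records between
#' variants, indexed for fast partner lookup by rsID. Storage is symmetric:
#' each input pair (a, b) is queryable from both sides. The canonical r2
#' thresholds used throughout the package are 0.2, 0.4, 0.6, 0.8 and 1;
#' the comparator is strict (r2 > t) below 1 and equality at t = 1.
#'
#' @slot pairs data.frame with columns `rsid`, `partner`, `r2`, `dprime`
#'   (symmetric closure of the input pairs).
#' @slot index named list mapping each rsID to its row indices in `pairs`.
#' @seealso [LDTable()], [ldPartners()], [independencePrune()]
#' @exportClass LDTable
setClass("LDTable",
  slots = c(pairs = "data.frame", index = "list")
)

setValidity("LDTable", function(object) {
  p <- object@pairs
  need <- c("rsid", "partner", "r2", "dprime")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (nrow(p) && (any(p$r2 < 0) || any(p$r2 > 1)))
    return("r2 values must lie in [0, 1]")
  if (nrow(p) && any(p$rsid == p$partner))
    return("self-pairs (rsid == partner) are not allowed")
  TRUE
})

#' Quartile bin scheme for matched null construction
#'
#' A 4 x 4 grid of bins over (distance to nearest TSS, LD-partner count),
#' with edges at the 25th/50th/75th percentiles of the input SNPs' two
#' statistics and the tabulated per-bin input counts that every matched
#' random set must reproduce exactly.
#'
#' @slot tssEdges numeric(3), quartile cut points of TSS distance (bp).
#' @slot ldEdges numeric(3), quartile cut points of LD-partner count.
#' @slot inputCounts 4 x 4 integer matrix; rows are TSS-distance bins
#'   (nearest first), columns LD-partner-count bins (fewest first).
#' @slot r2Threshold the r2 cutoff used for the partner counts.
#' @seealso [buildBinScheme()], [assignBin()], [sampleMatchedSets()]
#' @exportClass BinScheme
setClass("BinScheme",
  slots = c(
    tssEdges = "numeric",
    ldEdges = "numeric",
    inputCounts = "matrix",
    r2Threshold = "numeric"
  )
)

setValidity("BinScheme", function(object) {
  if (length(object@tssEdges) != 3L || length(object@ldEdges) != 3L)
    return("tssEdges and ldEdges must each have length 3")
  if (is.unsorted(object@tssEdges) || is.unsorted(object@ldEdges))
    return("bin edges must be non-decreasing")
  if (!identical(dim(object@inputCounts), c(4L, 4L)))
    return("inputCounts must be a 4 x 4 matrix")
  if (any(object@inputCounts < 0))
    return("inputCounts must be non-negative")
  TRUE
})

#' Matched random SNP sets
#'
#' The Monte Carlo null: `nSets` random draws from the platform catalog,
#' each reproducing the input SNPs' per-bin counts exactly. Members are
#' stored as integer indices into the platform the sets were drawn from;
#' draws are without replacement within a set and independent across sets,
#' fully reproducible from the seed.
#'
#' @slot sets integer matrix, one row per set, one column per member.
#' @slot columnBin integer vector giving each column's bin id (1..16).
#' @slot platformRsid rsIDs of the platform catalog the indices refer to.
#' @slot seed the master seed the sets were derived from.
#' @seealso [sampleMatchedSets()], [setMembers()]
#' @exportClass MatchedSets
setClass("MatchedSets",
  slots = c(
    sets = "matrix",
    columnBin = "integer",
    platformRsid = "character",
    seed = "integer"
  )
)

setValidity("MatchedSets", function(object) {
  if (ncol(object@sets) != length(object@columnBin))
    return("columnBin length must equal the number of set columns")
  if (nrow(object@sets) &&
      (any(object@sets < 1L) || any(object@sets > length(object@platformRsid))))
    return("set members must index into platformRsid")
  TRUE
})

#' Enrichment test result for one annotation track
#'
#' Observed collapsed-locus overlap count, the Monte Carlo null distribution
#' of counts, and the empirical exceedance p-value. When no null set reaches
#' the observed count the p-value is reported as the bound `< 1/n` rather
#' than zero (`pIsBound = TRUE`; `pValue` then stores `1/n`).
#'
#' @slot trackName annotation track label.
#' @slot observed observed number of distinct overlapping loci ("OrigLoci").
#' @slot nullCounts integer vector of per-set null overlap counts.
#' @slot exceedances number of null counts >= observed ("Rand>=Orig").
#' @slot nSets number of matched random sets.
#' @slot pValue empirical p (`exceedances/nSets`, or `1/nSets` when bound).
#' @slot pIsBound TRUE when no null count reached the observed value.
#' @slot nullMean mean of the null counts ("Random_Avg").
#' @slot r2Threshold LD expansion cutoff used.
#' @seealso [runEnrichment()], [empiricalP()], [formatPValue()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  slots = c(
    trackName = "character",
    observed = "integer",
    nullCounts = "integer",
    exceedances = "integer",
    nSets = "integer",
    pValue = "numeric",
    pIsBound = "logical",
    nullMean = "numeric",
    r2Threshold = "numeric"
  )
)

setValidity("EnrichmentResult", function(object) {
  if (object@nSets != length(object@nullCounts))
    return("nSets must equal length(nullCounts)")
  if (object@exceedances != sum(object@nullCounts >= object@observed))
    return("exceedances must equal the number of null counts >= observed")
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

#' A full enrichment run over one or more tracks
#'
#' Bundles the per-track [EnrichmentResult-class] objects of one pipeline
#' run together with the bin scheme and run parameters. All tracks in one
#' run are tested against byte-identical matched null sets.
#'
#' @slot results list of [EnrichmentResult-class], one per track.
#' @slot scheme the [BinScheme-class] used for matching.
#' @slot nSets,r2Threshold,seed run parameters.
#' @seealso [runEnrichment()], [resultsTable()]
#' @exportClass EnrichmentRun
setClass("EnrichmentRun",
  slots = c(
    results = "list",
    scheme = "BinScheme",
    nSets = "integer",
    r2Threshold = "numeric",
    seed = "integer"
  )
)

#' Locus for the circular annotation-shift test
#'
#' One risk locus: the index SNP plus its LD partners, with boundaries set
#' by the outermost member positions extended on each side by twice the
#' median annotation interval length (clipped at the chromosome start).
#' The locus is treated as a circle of `end - start + 1` bases when
#' annotations are shifted.
#'
#' @slot chrom chromosome name.
#' @slot memberRsid member rsIDs (index SNP first).
#' @slot memberPos 1-based member positions.
#' @slot start,end 1-based inclusive locus bounds.
#' @seealso [defineShiftLocus()], [shiftTest()]
#' @exportClass ShiftLocus
setClass("ShiftLocus",
  slots = c(
    chrom = "character",
    memberRsid = "character",
    memberPos = "integer",
    start = "integer",
    end = "integer"
  )
)

setValidity("ShiftLocus", function(object) {
  if (!length(object@memberPos)) return("a shift locus needs >= 1 member")
  if (object@start < 1L || object@start > object@end)
    return("locus bounds must satisfy 1 <= start <= end")
  if (any(object@memberPos < object@start) || any(object@memberPos > object@end))
    return("locus bounds must contain every member position")
  TRUE
})

#' Result of the circular annotation-shift test
#'
#' @slot observed loci overlapping the unshifted annotation.
#' @slot iterationCounts per-iteration overlapping-locus counts.
#' @slot pValue fraction of iterations with count >= observed (or > when
#'   `comparator = "greater"`).
#' @slot iterations,seed run parameters.
#' @slot comparator `"geq"` (default) or `"greater"`.
#' @seealso [shiftTest()]
#' @exportClass ShiftResult
setClass("ShiftResult",
  slots = c(
    observed = "integer",
    iterationCounts = "integer",
    pValue = "numeric",
    iterations = "integer",
    seed = "integer",
    comparator = "character"
  )
)

#' Configuration of a synthetic toy study
#'
#' Defines a self-contained toy genome: a platform SNP catalog organised
#' into constant-r2 LD blocks, a TSS list, an annotation track covering a
#' fixed genome fraction, and an input SNP set with a plantable level of
#' enrichment. See [syntheticConfig()] for the fields and defaults.
#'
#' @seealso [syntheticConfig()], [generateStudy()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(
    nChrom = "integer",
    chromLen = "integer",
    nPlatform = "integer",
    blockLen = "integer",
    withinBlockR2 = "numeric",
    nTss = "integer",
    trackCoverage = "numeric",
    trackIntervalBp = "integer",
    nInput = "integer",
    plantedFraction = "numeric",
    plantMode = "character",
    mafMin = "numeric",
    mafMax = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  if (object@plantedFraction < 0 || object@plantedFraction > 1)
    return("plantedFraction must lie in [0, 1]")
  if (object@trackCoverage <= 0 || object@trackCoverage >= 1)
    return("trackCoverage must lie in (0, 1)")
  if (object@withinBlockR2 <= 0.8 || object@withinBlockR2 > 1)
    return("withinBlockR2 must lie in (0.8, 1] so block mates are partners at r2 > 0.8")
  if (!object@plantMode %in% c("index", "partner"))
    return("plantMode must be 'index' or 'partner'")
  if (object@mafMin < 0.05 || object@mafMax > 0.5 || object@mafMin > object@mafMax)
    return("MAF bounds must satisfy 0.05 <= mafMin <= mafMax <= 0.5")
  if (object@nInput > object@nPlatform)
    return("nInput cannot exceed nPlatform")
  TRUE
})

#' A generated synthetic study
#'
#' The in-memory form of one toy study: every object the enrichment
#' pipeline consumes, plus the configuration that produced it. Use
#' [writeStudy()] to materialise it in the package's file formats.
#'
#' @slot platform GRanges of platform SNPs (mcols: rsid, maf, block).
#' @slot input GRanges of input SNPs (mcols: rsid, maf, gwas_p, planted).
#' @slot ld the block-structured [LDTable-class].
#' @slot tss GRanges of transcription start sites.
#' @slot tracks named list of annotation-track GRanges.
#' @slot config the [SyntheticConfig-class] used.
#' @seealso [generateStudy()]
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  slots = c(
    platform = "GRanges",
    input = "GRanges",
    ld = "LDTable",
    tss = "GRanges",
    tracks = "list",
    config = "SyntheticConfig"
  )
)
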