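#' Expand index SNPs to LD-defined loci
#'
#' Each index SNP becomes a locus whose members are the index itself plus
#' all of its LD partners at the chosen threshold. A SNP with no partners
#' yields a singleton locus.
#'
#' @param indexRsids character vector of index SNP rsIDs.
#' @param ld an [LDTable-class].
#' @param r2Min LD threshold, default 0.8.
#' @return named list (one element per index SNP) of member rsID vectors;
#'   the index SNP is always the first member.
#' @export
expandToLoci <- function(indexRsids, ld, r2Min = 0.8) {
  loci <- lapply(indexRsids, function(v) unique(c(v, ldPartners(ld, v, r2Min))))
  names(loci) <- indexRsids
  loci
}

# union-find component count over loci sharing any member; `mem` is a list
# of member vectors (integer indices or rsID strings)
.collapseCount <- function(mem) {
  n <- length(mem)
  if (n <= 1L) return(n)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  u <- unlist(mem, use.names = FALSE)
  g <- rep.int(seq_len(n), lengths(mem))
  o <- order(u)
  u <- u[o]
  g <- g[o]
  for (t in which(u[-1L] == u[-length(u)])) {
    a <- findRoot(g[t])
    b <- findRoot(g[t + 1L])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), findRoot, integer(1L))))
}

#' Count distinct loci overlapping a track
#'
#' A locus hits the track when any of its members overlaps an interval.
#' Hitting loci whose member sets intersect are then collapsed (connected
#' components over shared members), so a region tagged by several index
#' SNPs through common LD partners is counted once. The count of
#' components is returned.
#'
#' @param loci list of member-rsID vectors, as from [expandToLoci()].
#' @param track normalized track GRanges.
#' @param catalog variant GRanges resolving member rsIDs to positions.
#' @param permissive if TRUE, members absent from the catalog are dropped
#'   from overlap testing with a warning instead of raising an error.
#' @return integer count of distinct overlapping loci.
#' @export
countOverlappingLoci <- function(loci, track, catalog, permissive = FALSE) {
  if (!length(loci)) return(0L)
  catRsid <- variantRsid(catalog)
  allMem <- unique(unlist(loci, use.names = FALSE))
  hitIdx <- match(allMem, catRsid)
  if (anyNA(hitIdx)) {
    missing <- allMem[is.na(hitIdx)]
    if (!permissive)
      stop("member rsID(s) not resolvable to a position: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    warning(sprintf("dropping %d member rsID(s) without a known position",
                    length(missing)))
  }
  snpHit <- logical(length(allMem))
  ok <- !is.na(hitIdx)
  snpHit[ok] <- variantOverlaps(catalog[hitIdx[ok]], track)
  names(snpHit) <- allMem
  locusHit <- vapply(loci, function(m) any(snpHit[m]), logical(1L))
  .collapseCount(loci[locusHit])
}

#' Empirical exceedance p-value
#'
#' `r = #\{null counts >= observed\}` and `p = r/n`. When no null count
#' reaches the observed value the result is the bound `p < 1/n` (flagged
#' via `pIsBound`), never an exact zero.
#'
#' @param observed observed overlap count.
#' @param nullCounts non-empty integer vector of null counts.
#' @return list with `exceedances`, `nSets`, `pValue`, `pIsBound`.
#' @examples
#' empiricalP(12, c(rep(0, 9998), 12, 13))$pValue  # 2e-04
#' @export
empiricalP <- function(observed, nullCounts) {
  n <- length(nullCounts)
  if (!n) stop("the null distribution is empty")
  r <- sum(nullCounts >= observed)
  list(exceedances = as.integer(r), nSets = as.integer(n),
       pValue = if (r > 0L) r / n else 1 / n, pIsBound = r == 0L)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param nTracks number of tracks tested (>= 1).
#' @return `alpha / nTracks`.
#' @examples
#' bonferroniThreshold(0.05, 125)  # 4e-04
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTracks) {
  if (nTracks < 1L) stop("nTracks must be >= 1")
  alpha / nTracks
}

#' Format an empirical p-value for reporting
#'
#' @param x an [EnrichmentResult-class], [ShiftResult-class], or the list
#'   returned by [empiricalP()].
#' @return character such as `"0.0002"` or `"< 0.0001"`.
#' @export
formatPValue <- function(x) {
  if (is(x, "EnrichmentResult"))
    x <- list(pValue = x@pValue, pIsBound = x@pIsBound)
  if (is(x, "ShiftResult"))
    x <- list(pValue = x@pValue, pIsBound = FALSE)
  val <- format(x$pValue, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  if (isTRUE(x$pIsBound)) paste("<", val) else val
}

#' Run the Monte Carlo enrichment test
#'
#' The full test for one input SNP set against one or more annotation
#' tracks: build the quartile bin scheme from the input, draw `nSets`
#' matched random sets from the platform once, expand every set (input
#' and null alike) to LD loci, and for each track count distinct
#' overlapping loci and compute the empirical exceedance p-value. All
#' tracks are tested against the identical null sets.
#'
#' Inputs are assumed already curated (HLA exclusion, independence
#' pruning, duplicate-position dropping and MAF filtering; see
#' [excludeRegion()], [independencePrune()], [dropDuplicatePositions()],
#' [mafFilter()]).
#'
#' @param input curated input variant GRanges (>= 4 SNPs).
#' @param platform curated platform variant GRanges.
#' @param tracks a track GRanges or a (preferably named) list of them.
#' @param tss TSS GRanges.
#' @param ld an [LDTable-class].
#' @param r2Threshold LD expansion threshold, default 0.8.
#' @param nSets number of matched random sets, default 10000.
#' @param seed master RNG seed.
#' @param permissive drop LD partners without a catalog position instead
#'   of erroring (default FALSE).
#' @return an [EnrichmentRun-class].
#' @export
runEnrichment <- function(input, platform, tracks, tss, ld,
                          r2Threshold = 0.8, nSets = 10000, seed = 1,
                          permissive = FALSE) {
  if (is(tracks, "GRanges")) tracks <- list(tracks)
  trackNames <- names(tracks)
  if (is.null(trackNames)) trackNames <- rep(NA_character_, length(tracks))
  fallback <- vapply(tracks, trackName, character(1L))
  trackNames <- ifelse(is.na(trackNames) | trackNames == "",
                       ifelse(is.na(fallback),
                              paste0("track", seq_along(tracks)), fallback),
                       trackNames)

  scheme <- buildBinScheme(input, tss, ld, r2Threshold)
  ms <- sampleMatchedSets(platform, scheme, tss, ld, nSets, seed)

  # position catalog: platform first (so set indices are catalog indices),
  # then any input SNPs not on the platform
  catalog <- platform
  extra <- !(variantRsid(input) %in% variantRsid(platform))
  if (any(extra)) {
    keep <- intersect(c("rsid", "maf", "gwas_p"),
                      names(S4Vectors::mcols(platform)))
    add <- input[extra]
    S4Vectors::mcols(add) <- S4Vectors::mcols(add)[keep]
    S4Vectors::mcols(catalog) <- S4Vectors::mcols(catalog)[keep]
    catalog <- c(catalog, add)
  }
  catRsid <- variantRsid(catalog)
  lookup <- stats::setNames(seq_along(catRsid), catRsid)

  droppedAny <- FALSE
  memberIdx <- lapply(seq_along(catRsid), function(i) {
    pr <- ldPartners(ld, catRsid[i], r2Threshold)
    j <- lookup[pr]
    if (anyNA(j)) {
      if (!permissive)
        stop("member rsID(s) not resolvable to a position: ",
             paste(utils::head(pr[is.na(j)], 5L), collapse = ", "))
      droppedAny <<- TRUE
      j <- j[!is.na(j)]
    }
    c(i, unname(j))
  })
  if (droppedAny)
    warning("some LD partners had no catalog position and were dropped")

  inputIdx <- unname(lookup[variantRsid(input)])
  countSet <- function(idx, locusHit) {
    h <- idx[locusHit[idx]]
    if (length(h) <= 1L) return(length(h))
    .collapseCount(memberIdx[h])
  }

  results <- vector("list", length(tracks))
  for (t in seq_along(tracks)) {
    snpHit <- variantOverlaps(catalog, tracks[[t]])
    locusHit <- vapply(memberIdx, function(m) any(snpHit[m]), logical(1L))
    observed <- countSet(inputIdx, locusHit)
    nulls <- vapply(seq_len(numSets(ms)),
                    function(s) countSet(ms@sets[s, ], locusHit), integer(1L))
    ep <- empiricalP(observed, nulls)
    results[[t]] <- new("EnrichmentResult",
      trackName = trackNames[t],
      observed = as.integer(observed),
      nullCounts = nulls,
      exceedances = ep$exceedances,
      nSets = ep$nSets,
      pValue = ep$pValue,
      pIsBound = ep$pIsBound,
      nullMean = mean(nulls),
      r2Threshold = r2Threshold)
  }
  names(results) <- trackNames
  new("EnrichmentRun", results = results, scheme = scheme,
      nSets = as.integer(nSets), r2Threshold = r2Threshold,
      seed = as.integer(seed))
}

#' Tabulate an enrichment run
#'
#' One row per track, with the observed locus count ("OrigLoci"), the
#' number of null sets reaching it ("RandGeOrig"), the null mean
#' ("Random_Avg") and the empirical p-value, plus run parameters.
#'
#' @param run an [EnrichmentRun-class].
#' @return data.frame.
#' @export
resultsTable <- function(run) {
  do.call(rbind, lapply(run@results, function(r) {
    data.frame(track = r@trackName,
               OrigLoci = r@observed,
               RandGeOrig = r@exceedances,
               Random_Avg = r@nullMean,
               pValue = formatPValue(r),
               r2_threshold = r@r2Threshold,
               n_sets = r@nSets,
               seed = run@seed,
               stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Null-count histogram of one track's result
#'
#' @param result an [EnrichmentResult-class].
#' @return data.frame with columns `count` and `frequency`.
#' @export
nullHistogram <- function(result) {
  tab <- table(result@nullCounts)
  data.frame(count = as.integer(names(tab)),
             frequency = as.integer(tab),
             row.names = NULL)
}
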