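#' Curate an input SNP list
#'
#' The standard curation chain for the input set: exclude the HLA region,
#' prune to LD independence (keep the most significant member of every
#' correlated group), and optionally location-prune so no two survivors
#' lie within `minSeparation` of each other. Returns the survivors plus a
#' per-stage bookkeeping table (counts are conserved: in = out + removed
#' at every stage).
#'
#' @param input variant GRanges.
#' @param ld an [LDTable-class].
#' @param r2Min LD-independence threshold, default 0.8.
#' @param region exclusion region, default [hlaRegion()].
#' @param locationPrune also enforce a minimum pairwise separation.
#' @param minSeparation separation in bp, default 1 Mb.
#' @return list with `variants` and a `log` data.frame (stage, in, out,
#'   removed).
#' @export
preprocessInput <- function(input, ld, r2Min = 0.8, region = hlaRegion(),
                            locationPrune = FALSE, minSeparation = 1e6) {
  log <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer(), n_removed = integer())
  step <- function(name, before, after) {
    rbind(log, data.frame(stage = name, n_in = length(before),
                          n_out = length(after),
                          n_removed = length(before) - length(after)))
  }
  v1 <- excludeRegion(input, region)
  log <- step("hla_exclusion", input, v1)
  v2 <- independencePrune(v1, ld, r2Min)
  log <- step("independence_prune", v1, v2)
  if (locationPrune) {
    v3 <- locationPrune(v2, minSeparation)
    log <- step("location_prune", v2, v3)
    v2 <- v3
  }
  list(variants = v2, log = log)
}

#' Curate a platform sampling frame
#'
#' Exclude the HLA region, drop every variant at a duplicated start
#' position, and keep only variants with MAF at or above the cutoff.
#'
#' @param platform variant GRanges.
#' @param region exclusion region, default [hlaRegion()].
#' @param minMaf inclusive MAF cutoff, default 0.05.
#' @return list with `variants` and a `log` data.frame.
#' @export
preprocessPlatform <- function(platform, region = hlaRegion(),
                               minMaf = 0.05) {
  v1 <- excludeRegion(platform, region)
  v2 <- dropDuplicatePositions(v1)
  v3 <- mafFilter(v2, minMaf)
  list(variants = v3, log = data.frame(
    stage = c("hla_exclusion", "duplicate_position_drop", "maf_filter"),
    n_in = c(length(platform), length(v1), length(v2)),
    n_out = c(length(v1), length(v2), length(v3)),
    n_removed = c(length(platform) - length(v1), length(v1) - length(v2),
                  length(v2) - length(v3))))
}

#' Run the full enrichment pipeline and write results
#'
#' End-to-end driver: curate the input and platform, run the matched
#' Monte Carlo enrichment test at one or more r2 thresholds (rebuilding
#' the bin scheme and null sets per threshold), optionally run the
#' circular annotation-shift test, and write a results table, per-track
#' null histograms and a run log to `outDir`. All file arguments also
#' accept already-loaded objects.
#'
#' @param input variant GRanges or path (see [readVariants()]).
#' @param platform variant GRanges, path, or list/vector of paths whose
#'   union forms the sampling frame.
#' @param tracks named list of track GRanges, or vector of BED paths.
#' @param tss TSS GRanges or path.
#' @param ld an [LDTable-class] or path.
#' @param outDir output directory.
#' @param r2Thresholds LD thresholds to run, default 0.8.
#' @param nSets matched sets per run, default 10000.
#' @param seed master seed.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param locationPrune,minSeparation input location pruning (off by
#'   default).
#' @param permissive drop unresolvable LD partners instead of erroring.
#' @param shift also run the shift test per track at the first threshold.
#' @param shiftIterations iterations for the shift test, default 10000.
#' @return invisibly, a list with `runs` (one [EnrichmentRun-class] per
#'   threshold), `table` (combined results data.frame), `log`, and
#'   `shift` results when requested.
#' @export
runPipeline <- function(input, platform, tracks, tss, ld, outDir,
                        r2Thresholds = 0.8, nSets = 10000, seed = 1,
                        alpha = 0.05, locationPrune = FALSE,
                        minSeparation = 1e6, permissive = FALSE,
                        shift = FALSE, shiftIterations = 10000) {
  if (is.character(input)) input <- readVariants(input)
  if (is.character(platform)) {
    frames <- lapply(platform, readVariants)
    platform <- frames[[1L]]
    for (f in frames[-1L]) {
      new <- !(variantRsid(f) %in% variantRsid(platform))
      platform <- c(platform, f[new])
    }
  }
  if (is.character(tss)) tss <- readTss(tss)
  if (is.character(ld)) ld <- readLDTable(ld)
  if (is.character(tracks)) {
    paths <- tracks
    tracks <- lapply(paths, readBed)
    names(tracks) <- vapply(tracks, trackName, character(1L))
  }
  if (is(tracks, "GRanges")) tracks <- list(track = tracks)

  inp <- preprocessInput(input, ld, r2Min = max(r2Thresholds[1L], 0.8),
                         locationPrune = locationPrune,
                         minSeparation = minSeparation)
  plat <- preprocessPlatform(platform)
  log <- rbind(cbind(source = "input", inp$log),
               cbind(source = "platform", plat$log))

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  tables <- list()
  for (r2 in r2Thresholds) {
    run <- runEnrichment(inp$variants, plat$variants, tracks, tss, ld,
                         r2Threshold = r2, nSets = nSets, seed = seed,
                         permissive = permissive)
    runs[[as.character(r2)]] <- run
    tab <- resultsTable(run)
    tab$bonferroni_threshold <- bonferroniThreshold(alpha, length(tracks))
    tables[[as.character(r2)]] <- tab
    for (r in run@results) {
      utils::write.table(
        nullHistogram(r),
        file.path(outDir, sprintf("null_hist_%s_r2_%s.tsv", r@trackName, r2)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  table <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  utils::write.table(table, file.path(outDir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(log, file.path(outDir, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  shiftRes <- NULL
  if (shift) {
    extra <- !(variantRsid(inp$variants) %in% variantRsid(plat$variants))
    catalog <- plat$variants
    if (any(extra)) {
      add <- inp$variants[extra]
      keep <- intersect(names(S4Vectors::mcols(catalog)),
                        names(S4Vectors::mcols(add)))
      S4Vectors::mcols(add) <- S4Vectors::mcols(add)[keep]
      S4Vectors::mcols(catalog) <- S4Vectors::mcols(catalog)[keep]
      catalog <- c(catalog, add)
    }
    shiftRes <- lapply(tracks, function(tr) {
      loci <- buildShiftLoci(variantRsid(inp$variants), ld,
                             catalog = catalog,
                             track = tr, r2Min = r2Thresholds[1L],
                             permissive = TRUE)
      shiftTest(loci, tr, iterations = shiftIterations, seed = seed)
    })
    st <- data.frame(
      track = names(tracks),
      n_loci = length(inp$variants),
      observed = vapply(shiftRes, function(s) s@observed, integer(1L)),
      pValue = vapply(shiftRes, function(s) s@pValue, numeric(1L)),
      iterations = shiftIterations, seed = seed, row.names = NULL)
    utils::write.table(st, file.path(outDir, "shift_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(runs = runs, table = table, log = log, shift = shiftRes))
}

#' Generate a synthetic study on disk
#'
#' Wraps [generateStudy()] and [writeStudy()].
#'
#' @param cfg a [SyntheticConfig-class] (see [syntheticConfig()]).
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
simulateStudy <- function(cfg, dir) {
  writeStudy(generateStudy(cfg), dir)
}
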