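setMethod("show", "LDTable", function(object) {
  nPairs <- nrow(object@pairs) / 2L
  cat(sprintf("LDTable with %d pair(s) over %d variant(s)\n",
              nPairs, length(object@index)))
  if (nPairs)
    cat(sprintf("  r2 range: [%.3g, %.3g]\n",
                min(object@pairs$r2), max(object@pairs$r2)))
})

setMethod("show", "BinScheme", function(object) {
  cat("BinScheme (4 x 4 quartile grid)\n")
  cat("  TSS-distance edges (bp):",
      paste(signif(object@tssEdges, 4), collapse = ", "), "\n")
  cat("  LD-partner-count edges:",
      paste(signif(object@ldEdges, 4), collapse = ", "), "\n")
  cat(sprintf("  input SNPs: %d\n", sum(object@inputCounts)))
  print(object@inputCounts)
})

setMethod("show", "MatchedSets", function(object) {
  cat(sprintf("MatchedSets: %d set(s) of %d SNP(s) (seed %d)\n",
              nrow(object@sets), ncol(object@sets), object@seed))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult for track '%s' (r2 > %s)\n",
              object@trackName, format(object@r2Threshold)))
  cat(sprintf("  observed loci: %d | null mean: %.3f over %d sets\n",
              object@observed, object@nullMean, object@nSets))
  cat(sprintf("  empirical p = %s\n", formatPValue(object)))
})

setMethod("show", "EnrichmentRun", function(object) {
  cat(sprintf("EnrichmentRun: %d track(s), %d matched sets, r2 > %s, seed %d\n",
              length(object@results), object@nSets,
              format(object@r2Threshold), object@seed))
  for (r in object@results)
    cat(sprintf("  %-30s observed %3d  null mean %7.3f  p = %s\n",
                r@trackName, r@observed, r@nullMean, formatPValue(r)))
})

setMethod("show", "ShiftLocus", function(object) {
  cat(sprintf("ShiftLocus %s:%d-%d (circumference %d bp, %d member(s))\n",
              object@chrom, object@start, object@end,
              circumference(object), length(object@memberPos)))
})

setMethod("show", "ShiftResult", function(object) {
  cat(sprintf(
    "ShiftResult: observed %d locus/loci | p = %s over %d iterations\n",
    object@observed, format(object@pValue), object@iterations))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d x %.3g bp chromosome(s), %d platform SNPs, %d input\n",
    object@nChrom, as.numeric(object@chromLen), object@nPlatform,
    object@nInput))
  cat(sprintf(
    "  LD blocks %d bp @ r2 = %.2f | coverage %.3f | planted %.2f (%s) | seed %d\n",
    object@blockLen, object@withinBlockR2, object@trackCoverage,
    object@plantedFraction, object@plantMode, object@seed))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf(
    "SyntheticStudy: %d platform SNPs, %d input SNPs, %d track(s), %d TSS\n",
    length(object@platform), length(object@input), length(object@tracks),
    length(object@tss)))
  show(object@config)
})
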