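#' Configure a synthetic toy study
#'
#' Defaults describe a scaled-down human-like study: a 20-Mb genome
#' (2 chromosomes of 10 Mb), a genotyping platform of 6,000 SNPs (about
#' one per 3.3 kb, typical chip density), 20-kb LD blocks with constant
#' within-block r2 = 0.9 and no between-block LD, 200 TSS (one per 100
#' kb), one annotation track built from 300-bp intervals (DNase-peak
#' sized) covering 3% of the genome, and 30 input SNPs. `plantedFraction`
#' of the input SNPs are forced to overlap the track: mode `"index"`
#' relocates the input SNP itself into a covered base, mode `"partner"`
#' leaves the input SNP outside but places a same-block LD partner inside
#' (the tag-SNP detection path). Platform MAFs are uniform on
#' [mafMin, mafMax]; input GWAS p-values are log-uniform on [1e-12, 1e-8].
#'
#' @param nChrom,chromLen genome shape.
#' @param nPlatform platform catalog size.
#' @param blockLen,withinBlockR2 LD block structure (`withinBlockR2` must
#'   exceed 0.8 so block mates are partners at the default threshold).
#' @param nTss number of transcription start sites.
#' @param trackCoverage,trackIntervalBp annotation track geometry.
#' @param nInput,plantedFraction,plantMode input SNP set.
#' @param mafMin,mafMax MAF sampling bounds (within [0.05, 0.5]).
#' @param seed master seed; all randomness flows from it via named
#'   substreams.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nChrom = 2, chromLen = 1e7, nPlatform = 6000,
                            blockLen = 20000, withinBlockR2 = 0.9,
                            nTss = 200, trackCoverage = 0.03,
                            trackIntervalBp = 300, nInput = 30,
                            plantedFraction = 0,
                            plantMode = c("index", "partner"),
                            mafMin = 0.05, mafMax = 0.5, seed = 1) {
  new("SyntheticConfig",
      nChrom = as.integer(nChrom), chromLen = as.integer(chromLen),
      nPlatform = as.integer(nPlatform), blockLen = as.integer(blockLen),
      withinBlockR2 = withinBlockR2, nTss = as.integer(nTss),
      trackCoverage = trackCoverage,
      trackIntervalBp = as.integer(trackIntervalBp),
      nInput = as.integer(nInput), plantedFraction = plantedFraction,
      plantMode = match.arg(plantMode),
      mafMin = mafMin, mafMax = mafMax, seed = as.integer(seed))
}

#' Generate a synthetic study
#'
#' Produces every object the enrichment pipeline consumes: a platform
#' SNP catalog with unique uniform positions organised into constant-r2
#' LD blocks, the corresponding pairwise LD table, a TSS list, one
#' annotation track assembled from fixed-size windows hitting the target
#' coverage, and an input SNP set with the configured planted enrichment.
#' Identical configurations (including the seed) yield identical studies.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return a [SyntheticStudy-class].
#' @export
generateStudy <- function(cfg) {
  validObject(cfg)
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(cfg@seed)
  streams <- sample.int(2147483646L, 6L)  # platform, track, input, maf, gwasp, tss

  nPer <- .splitCount(cfg@nPlatform, cfg@nChrom)
  chroms <- paste0("chr", seq_len(cfg@nChrom))

  # track: fixed-size windows sampled without replacement across the genome
  w <- cfg@trackIntervalBp
  winPerChrom <- cfg@chromLen %/% w
  totalWin <- winPerChrom * cfg@nChrom
  k <- max(1L, as.integer(round(cfg@trackCoverage * cfg@nChrom *
                                  as.numeric(cfg@chromLen) / w)))
  if (k > totalWin)
    stop(sprintf(
      "infeasible geometry: coverage %.3f needs %d windows of %d bp but only %d fit",
      cfg@trackCoverage, k, w, totalWin))
  set.seed(streams[2L])
  win <- sort(sample.int(totalWin, k))
  winChrom <- (win - 1L) %/% winPerChrom + 1L
  winLocal <- (win - 1L) %% winPerChrom
  track <- normalizeTrack(
    GenomicRanges::GRanges(chroms[winChrom],
                           IRanges::IRanges(start = winLocal * w + 1L,
                                            width = w)),
    name = "synthetic_track")
  coveredKey <- win  # window ids fully covered by the track

  # platform positions: uniform, unique within chromosome
  set.seed(streams[1L])
  pos <- integer(0); chromIdx <- integer(0)
  for (ci in seq_len(cfg@nChrom)) {
    p <- sample.int(cfg@chromLen, nPer[ci])
    pos <- c(pos, p)
    chromIdx <- c(chromIdx, rep.int(ci, nPer[ci]))
  }

  # input SNPs and planting (positions may move; blocks assigned after)
  set.seed(streams[3L])
  inputSel <- sort(sample.int(cfg@nPlatform, cfg@nInput))
  nPlant <- as.integer(round(cfg@plantedFraction * cfg@nInput))
  planted <- logical(cfg@nInput)
  if (nPlant > 0L) {
    planted[seq_len(nPlant)] <- TRUE
    usedKey <- paste(chromIdx, pos)
    drawCovered <- function() {
      repeat {
        wi <- coveredKey[sample.int(length(coveredKey), 1L)]
        ci <- (wi - 1L) %/% winPerChrom + 1L
        p <- ((wi - 1L) %% winPerChrom) * w + sample.int(w, 1L)
        key <- paste(ci, p)
        if (!key %in% usedKey) return(list(chrom = ci, pos = p, key = key))
      }
    }
    for (j in seq_len(nPlant)) {
      i <- inputSel[j]
      spot <- drawCovered()
      if (cfg@plantMode == "index") {
        chromIdx[i] <- spot$chrom
        pos[i] <- spot$pos
        usedKey[i] <- spot$key
      } else {
        # keep the index SNP outside the track but inside the same block,
        # and relocate a non-input platform SNP onto the covered base
        blockLo <- ((spot$pos - 1L) %/% cfg@blockLen) * cfg@blockLen
        repeat {
          cand <- blockLo + sample.int(min(cfg@blockLen,
                                           cfg@chromLen - blockLo), 1L)
          key <- paste(spot$chrom, cand)
          inside <- ((cand - 1L) %/% w) + (spot$chrom - 1L) * winPerChrom + 1L
          onTrack <- (((cand - 1L) %/% w) %in% winLocal[winChrom == spot$chrom])
          if (!onTrack && !key %in% usedKey) break
        }
        chromIdx[i] <- spot$chrom
        pos[i] <- cand
        usedKey[i] <- key
        donor <- sample(setdiff(seq_len(cfg@nPlatform), inputSel), 1L)
        chromIdx[donor] <- spot$chrom
        pos[donor] <- spot$pos
        usedKey[donor] <- spot$key
      }
    }
  }

  set.seed(streams[4L])
  maf <- stats::runif(cfg@nPlatform, cfg@mafMin, cfg@mafMax)
  set.seed(streams[5L])
  gwasP <- 10^(-stats::runif(cfg@nInput, 8, 12))

  ord <- order(chromIdx, pos)
  rank <- match(seq_len(cfg@nPlatform), ord)
  rsid <- sprintf("rs%06d", seq_len(cfg@nPlatform))
  block <- (chromIdx[ord] - 1L) * (cfg@chromLen %/% cfg@blockLen + 1L) +
    (pos[ord] - 1L) %/% cfg@blockLen
  platform <- GenomicRanges::GRanges(
    chroms[chromIdx[ord]], IRanges::IRanges(start = pos[ord], width = 1L))
  S4Vectors::mcols(platform)$rsid <- rsid[ord]
  S4Vectors::mcols(platform)$maf <- maf[ord]
  S4Vectors::mcols(platform)$block <- block

  # pairwise LD: every within-block pair at the configured r2
  byBlock <- split(seq_along(platform), block)
  pairA <- integer(0); pairB <- integer(0)
  for (idx in byBlock) {
    m <- length(idx)
    if (m < 2L) next
    cmb <- utils::combn(idx, 2L)
    pairA <- c(pairA, cmb[1L, ])
    pairB <- c(pairB, cmb[2L, ])
  }
  ldPairs <- data.frame(
    rsid_a = S4Vectors::mcols(platform)$rsid[pairA],
    rsid_b = S4Vectors::mcols(platform)$rsid[pairB],
    r2 = rep(cfg@withinBlockR2, length(pairA)),
    dprime = rep(1, length(pairA)),
    stringsAsFactors = FALSE)
  ld <- LDTable(ldPairs)

  set.seed(streams[6L])
  tssChrom <- sample.int(cfg@nChrom, cfg@nTss, replace = TRUE)
  tssPos <- sample.int(cfg@chromLen, cfg@nTss, replace = TRUE)
  tss <- tssRanges(chroms[tssChrom], tssPos,
                   sprintf("gene%03d", seq_len(cfg@nTss)))

  input <- platform[rank[inputSel]]
  S4Vectors::mcols(input)$gwas_p <- gwasP
  S4Vectors::mcols(input)$planted <- planted

  new("SyntheticStudy", platform = platform, input = input, ld = ld,
      tss = tss, tracks = list(synthetic_track = track), config = cfg)
}

.splitCount <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' Expected matched-null overlap under independence
#'
#' The simple per-locus expectation when SNP placement and track
#' placement are independent: a locus with `k` same-block LD partners
#' hits a track of genome coverage `c` with probability
#' `1 - (1 - c)^(1 + k)`; the expectation is the sum over loci. Ignores
#' locus collapse (two sampled loci sharing a block count once), so it is
#' an upper bound that is tight when same-block co-sampling is rare; see
#' [expectedMatchedNullMean()] for the exact block-level expectation.
#'
#' @param partnerCounts integer vector, per-locus LD partner counts.
#' @param coverage track coverage as a genome fraction.
#' @return expected number of overlapping loci.
#' @examples
#' expectedNullOverlap(rep(0, 30), 0.01)  # 0.3
#' @export
expectedNullOverlap <- function(partnerCounts, coverage) {
  sum(1 - (1 - coverage)^(1 + partnerCounts))
}

#' Exact expected null mean for matched sets on a synthetic study
#'
#' Under block-constant LD, every locus's member set is exactly its LD
#' block, so a matched set's collapsed overlap count equals the number of
#' distinct sampled blocks that contain at least one track-overlapping
#' SNP. Because matched sampling is without replacement within each bin
#' and independent across bins, the probability that a given block goes
#' unsampled factorizes over bins hypergeometrically, giving the exact
#' expectation of the null count, collapse included.
#'
#' @param study a [SyntheticStudy-class].
#' @param scheme the [BinScheme-class] the matched sets are drawn under.
#' @param track a track GRanges; defaults to the study's first track.
#' @return exact expected matched-null overlap count.
#' @export
expectedMatchedNullMean <- function(study, scheme,
                                    track = study@tracks[[1L]]) {
  platform <- study@platform
  bins <- assignBin(platform, scheme, study@tss, study@ld)
  id <- .binId(bins[, 1L], bins[, 2L])
  need <- as.integer(t(scheme@inputCounts))
  nBin <- tabulate(id, nbins = 16L)
  snpHit <- variantOverlaps(platform, track)
  block <- S4Vectors::mcols(platform)$block
  membersByBlock <- split(seq_along(platform), block)
  blockHit <- vapply(membersByBlock, function(i) any(snpHit[i]), logical(1L))
  total <- 0
  for (bl in names(membersByBlock)[blockHit]) {
    members <- membersByBlock[[bl]]
    x <- tabulate(id[members], nbins = 16L)
    pMiss <- 1
    for (b in which(x > 0L)) {
      if (need[b] == 0L) next
      j <- seq_len(x[b]) - 1
      pMiss <- pMiss * prod((nBin[b] - need[b] - j) / (nBin[b] - j))
    }
    total <- total + (1 - pMiss)
  }
  total
}

#' Write a synthetic study to disk
#'
#' Emits the study in the package's standard file formats (variant and
#' TSS tables, LD table, BED tracks) plus a JSON manifest listing every
#' path and the generating configuration.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    platform = file.path(dir, "platform.tsv"),
    input = file.path(dir, "input_snps.tsv"),
    ld = file.path(dir, "ld_pairs.tsv"),
    tss = file.path(dir, "tss.tsv"))
  writeVariants(study@platform, paths$platform)
  writeVariants(study@input, paths$input)
  writeLDTable(study@ld, paths$ld)
  writeTss(study@tss, paths$tss)
  paths$tracks <- vapply(names(study@tracks), function(nm) {
    p <- file.path(dir, paste0(nm, ".bed"))
    writeBed(study@tracks[[nm]], p)
    p
  }, character(1L))
  cfg <- study@config
  cfgList <- stats::setNames(
    lapply(slotNames(cfg), function(s) slot(cfg, s)), slotNames(cfg))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(paths = paths, config = cfgList), manifest,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
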