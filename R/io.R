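#' Normalize chromosome names to the "chrN" dialect
#'
#' Bare names ("7", "X") gain the `chr` prefix; names already carrying it
#' are returned unchanged. All package readers apply this, so downstream
#' code sees a single dialect.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector in `chrN` form.
#' @examples
#' normalizeChrom(c("1", "chr2", "X"))
#' @export
normalizeChrom <- function(chrom) {
  chrom <- as.character(chrom)
  bare <- !startsWith(chrom, "chr")
  chrom[bare] <- paste0("chr", chrom[bare])
  chrom
}

#' Construct a variant GRanges
#'
#' Variants are width-1 GRanges at their 1-based position, with metadata
#' columns `rsid`, `maf` and `gwas_p`. MAF must lie in [0, 0.5] and the
#' GWAS p-value in (0, 1] when present.
#'
#' @param rsid character rsIDs (must be unique).
#' @param chrom chromosome names (any dialect; normalized to `chrN`).
#' @param pos 1-based positions (>= 1).
#' @param maf minor allele frequencies, `NA` when unknown.
#' @param gwasP reported GWAS p-values, `NA` when unknown.
#' @return GRanges with mcols `rsid`, `maf`, `gwas_p`.
#' @export
variantRanges <- function(rsid, chrom, pos, maf = NA_real_, gwasP = NA_real_) {
  n <- length(rsid)
  maf <- rep_len(as.numeric(maf), n)
  gwasP <- rep_len(as.numeric(gwasP), n)
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("variant positions must be integers >= 1")
  if (anyDuplicated(rsid))
    stop("duplicate rsIDs: ",
         paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  bad <- !is.na(maf) & (maf < 0 | maf > 0.5)
  if (any(bad))
    stop("MAF out of [0, 0.5] for: ", paste(rsid[bad], collapse = ", "))
  bad <- !is.na(gwasP) & (gwasP <= 0 | gwasP > 1)
  if (any(bad))
    stop("gwas_p out of (0, 1] for: ", paste(rsid[bad], collapse = ", "))
  gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                               IRanges::IRanges(start = pos, width = 1L))
  S4Vectors::mcols(gr)$rsid <- as.character(rsid)
  S4Vectors::mcols(gr)$maf <- maf
  S4Vectors::mcols(gr)$gwas_p <- gwasP
  gr
}

#' @rdname variantRanges
#' @param x a variant GRanges.
#' @export
variantRsid <- function(x) S4Vectors::mcols(x)$rsid

#' Read a variant table
#'
#' Tab-separated with a header line; mandatory columns `rsid`, `chrom`,
#' `pos`, optional `maf` and `gwas_p`. Rows failing validation are
#' reported with their line number; duplicated rsIDs are an error.
#'
#' @param path file path (plain or gzipped).
#' @return variant GRanges (see [variantRanges()]).
#' @export
readVariants <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("rsid", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop(sprintf("%s: invalid position on line %d (positions are 1-based integers)",
                 path, bad[1L] + 1L))
  maf <- if ("maf" %in% names(df)) suppressWarnings(as.numeric(df$maf)) else NA_real_
  gp <- if ("gwas_p" %in% names(df)) suppressWarnings(as.numeric(df$gwas_p)) else NA_real_
  variantRanges(df$rsid, df$chrom, pos, maf, gp)
}

#' Write a variant table
#'
#' @param x variant GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(x, path) {
  mc <- S4Vectors::mcols(x)
  col <- function(nm) if (nm %in% names(mc)) mc[[nm]] else rep(NA_real_, length(x))
  df <- data.frame(
    rsid = variantRsid(x),
    chrom = as.character(GenomicRanges::seqnames(x)),
    pos = GenomicRanges::start(x),
    maf = col("maf"),
    gwas_p = col("gwas_p")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS list
#'
#' Tab-separated with header; columns `chrom`, `pos` (1-based), optional
#' `name`.
#'
#' @param path file path.
#' @return width-1 GRanges sorted by (chrom, pos), with mcols `name`.
#' @export
readTss <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "pos"), names(df))
  if (length(miss))
    stop(sprintf("%s: missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop(sprintf("%s: invalid TSS position on line %d", path, bad[1L] + 1L))
  tssRanges(df$chrom, pos, if ("name" %in% names(df)) df$name else NA_character_)
}

#' @rdname readTss
#' @param chrom,pos,name site coordinates and optional labels.
#' @export
tssRanges <- function(chrom, pos, name = NA_character_) {
  gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                               IRanges::IRanges(start = as.integer(pos), width = 1L))
  S4Vectors::mcols(gr)$name <- rep_len(as.character(name), length(gr))
  sort(gr)
}

#' @rdname readTss
#' @param x TSS GRanges.
#' @param path output path.
#' @export
writeTss <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   pos = GenomicRanges::start(x),
                   name = S4Vectors::mcols(x)$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3+ annotation track
#'
#' Parses a headerless tab-separated BED file (0-based half-open
#' coordinates), converts to 1-based closed GRanges and normalizes:
#' intervals are sorted and overlapping or abutting intervals merged.
#' Extra BED columns are ignored. An empty file yields an empty track.
#'
#' @param path BED file path.
#' @param name track name; defaults to the file basename without `.bed`.
#' @return normalized GRanges; the name is stored in `metadata(x)$name`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t15\t30"), f)
#' readBed(f)  # one merged interval chr1:11-30
#' @export
readBed <- function(path, name = sub("\\.bed(\\.gz)?$", "", basename(path))) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$name <- name
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: malformed BED line %d: fewer than 3 tab-separated fields",
                 path, lineNo[which(nf < 3L)[1L]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s < 0L | e < 0L | s >= e)
  if (length(bad))
    stop(sprintf(
      "%s: malformed BED line %d: start/end must be non-negative integers with start < end",
      path, lineNo[bad[1L]]))
  gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                               IRanges::IRanges(start = s + 1L, end = e))
  normalizeTrack(gr, name = name)
}

#' Normalize an annotation track
#'
#' Sorts intervals and merges any that overlap or abut, so that no two
#' intervals on a chromosome touch. Idempotent; the covered-base set is
#' unchanged.
#'
#' @param x GRanges.
#' @param name optional track name to store in `metadata(x)$name`.
#' @return normalized GRanges.
#' @export
normalizeTrack <- function(x, name = trackName(x)) {
  out <- GenomicRanges::reduce(sort(x), min.gapwidth = 1L)
  S4Vectors::metadata(out)$name <- name
  out
}

#' @rdname normalizeTrack
#' @export
trackName <- function(x) {
  nm <- S4Vectors::metadata(x)$name
  if (is.null(nm)) NA_character_ else nm
}

#' Write a track as BED3
#'
#' @param x track GRanges (1-based closed; written 0-based half-open).
#' @param path output path.
#' @export
writeBed <- function(x, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1L,
                   end = GenomicRanges::end(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge annotation tracks into a union track
#'
#' The normalized union of the inputs: the covered-base set equals the
#' union of the inputs' covered-base sets. Used to build composite tracks
#' such as a ChIP-Seq peak union across many factors.
#'
#' @param tracks non-empty list of track GRanges.
#' @param name name of the union track.
#' @return normalized GRanges.
#' @export
mergeTracks <- function(tracks, name = "union") {
  if (!is.list(tracks) || !length(tracks))
    stop("'tracks' must be a non-empty list of GRanges")
  normalizeTrack(do.call(c, lapply(tracks, function(g) {
    S4Vectors::metadata(g) <- list()
    g
  })), name = name)
}

#' Does each variant fall inside the track?
#'
#' A variant overlaps when its 1-based position lies within a track
#' interval (BED half-open semantics: a variant at `pos` hits `[start,
#' end)` iff `start < pos <= end` in 0-based terms).
#'
#' @param v variant GRanges.
#' @param track normalized track GRanges.
#' @return logical vector along `v`.
#' @export
variantOverlaps <- function(v, track) {
  .overlapsAnyQuiet(v, track)
}

# overlapsAny without the "no sequence levels in common" warning: fully
# disjoint chromosome sets simply mean no overlaps
.overlapsAnyQuiet <- function(query, subject) {
  if (!length(subject) ||
      !length(intersect(GenomeInfoDb::seqlevels(query),
                        GenomeInfoDb::seqlevels(subject))))
    return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject)
}

#' Total covered bases of a track
#'
#' @param x track GRanges.
#' @return integer base count.
#' @export
coveredBases <- function(x) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(x, min.gapwidth = 1L))))
}
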