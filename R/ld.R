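#' Build an LD table from pairwise records
#'
#' Takes one row per unordered variant pair with its r-squared (and
#' optionally D') and stores the symmetric closure, indexed by rsID.
#' Duplicate records of the same pair are collapsed; conflicting r2
#' values for one pair are an error.
#'
#' @param pairs data.frame with columns `rsid_a`, `rsid_b`, `r2` and
#'   optionally `dprime`.
#' @return an [LDTable-class].
#' @examples
#' ld <- LDTable(data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9))
#' ldPartners(ld, "rs2", 0.8)
#' @export
LDTable <- function(pairs) {
  need <- c("rsid_a", "rsid_b", "r2")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("LD pairs need column(s): ", paste(miss, collapse = ", "))
  a <- as.character(pairs$rsid_a)
  b <- as.character(pairs$rsid_b)
  r2 <- as.numeric(pairs$r2)
  dp <- if ("dprime" %in% names(pairs)) as.numeric(pairs$dprime)
        else rep(NA_real_, length(a))
  if (any(a == b)) stop("LD self-pairs are not allowed")
  if (length(r2) && (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)))
    stop("r2 values must lie in [0, 1]")
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) {
    split_r2 <- split(r2, key)
    conflict <- vapply(split_r2, function(v) max(v) - min(v) > 1e-12, TRUE)
    if (any(conflict))
      stop("conflicting r2 for pair(s): ",
           paste(names(split_r2)[conflict], collapse = ", "))
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]; r2 <- r2[first]; dp <- dp[first]
  }
  sym <- data.frame(
    rsid = c(a, b), partner = c(b, a),
    r2 = c(r2, r2), dprime = c(dp, dp),
    stringsAsFactors = FALSE
  )
  idx <- split(seq_len(nrow(sym)), sym$rsid)
  new("LDTable", pairs = sym, index = idx)
}

#' Read an LD table from a tab-separated file
#'
#' Expected columns (with header): `rsid_a`, `rsid_b`, `r2`, optional
#' `dprime`. Plain and gzip/bgzip-compressed files are accepted.
#'
#' @param path file path.
#' @return an [LDTable-class].
#' @export
readLDTable <- function(path) {
  LDTable(utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

#' @rdname readLDTable
#' @param x an [LDTable-class].
#' @export
writeLDTable <- function(x, path) {
  p <- x@pairs
  keep <- p$rsid < p$partner
  utils::write.table(
    data.frame(rsid_a = p$rsid[keep], rsid_b = p$partner[keep],
               r2 = p$r2[keep], dprime = p$dprime[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# threshold comparator: strict above t for t < 1, equality at t = 1
.ldKeep <- function(r2, t) {
  if (t >= 1) r2 >= 1 - 1e-9 else r2 > t
}

#' LD partners of a variant
#'
#' Returns the rsIDs stored in LD with `rsid` at the given threshold. The
#' comparator follows the canonical threshold ladder: strictly greater
#' than `r2Min` for thresholds below 1, and equality for `r2Min = 1`.
#' Unknown rsIDs yield an empty set; the query never includes the variant
#' itself.
#'
#' @param x an [LDTable-class].
#' @param rsid a single rsID.
#' @param r2Min r2 threshold (canonically 0.2, 0.4, 0.6, 0.8 or 1).
#' @return character vector of partner rsIDs.
#' @export
ldPartners <- function(x, rsid, r2Min = 0.8) {
  rows <- x@index[[rsid]]
  if (is.null(rows)) return(character())
  rows <- rows[.ldKeep(x@pairs$r2[rows], r2Min)]
  x@pairs$partner[rows]
}

#' Number of LD partners, vectorized over rsIDs
#'
#' @inheritParams ldPartners
#' @param rsid character vector of rsIDs.
#' @return integer vector of partner counts (0 for unknown rsIDs).
#' @export
ldPartnerCount <- function(x, rsid, r2Min = 0.8) {
  idx <- x@index
  r2 <- x@pairs$r2
  vapply(rsid, function(v) {
    rows <- idx[[v]]
    if (is.null(rows)) 0L else sum(.ldKeep(r2[rows], r2Min))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Prune a variant list to LD-independent members
#'
#' Greedy clumping: variants are visited in order of ascending GWAS
#' p-value (ties broken by rsID); each visited variant is kept and all of
#' its yet-unkept partners above the r2 threshold are removed. Within
#' every correlated group only the most significant member survives, and
#' survivors are pairwise below the threshold. Input order is preserved.
#'
#' @param variants variant GRanges with `gwas_p` on every variant that is
#'   in LD with another input variant (missing values elsewhere are fine).
#' @param ld an [LDTable-class].
#' @param r2Min r2 threshold, default 0.8.
#' @return the surviving subset of `variants`, in input order.
#' @export
independencePrune <- function(variants, ld, r2Min = 0.8) {
  n <- length(variants)
  if (n <= 1L) return(variants)
  rsid <- variantRsid(variants)
  p <- S4Vectors::mcols(variants)$gwas_p
  inInput <- stats::setNames(seq_len(n), rsid)
  partnerIdx <- lapply(rsid, function(v) {
    hits <- inInput[ldPartners(ld, v, r2Min)]
    unname(hits[!is.na(hits)])
  })
  involved <- lengths(partnerIdx) > 0L
  if (any(involved & is.na(p)))
    stop("gwas_p required for correlated variant(s): ",
         paste(rsid[involved & is.na(p)], collapse = ", "))
  ord <- order(ifelse(is.na(p), Inf, p), rsid)
  keep <- logical(n)
  removed <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    keep[i] <- TRUE
    removed[partnerIdx[[i]]] <- TRUE
  }
  variants[keep]
}
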