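# Internal helpers shared across modules.

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (any case) and upper-cases X/Y/MT so that
#' "chr1", "Chr1" and "1" compare equal. No numeric reordering is implied;
#' comparisons elsewhere are string based.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  toupper(x)
}

# Deterministic display order: autosomes numerically, then X, Y, MT, then rest.
chrom_order_key <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(!is.na(n), n,
    ifelse(chrom == "X", 100, ifelse(chrom == "Y", 101, ifelse(chrom == "MT", 102, 103)))
  )
  key
}

# Order calls for stable output: chrom, start, end, sample.
call_order <- function(calls) {
  order(chrom_order_key(calls$chrom), calls$chrom, calls$start, calls$end, calls$sample_id)
}

cnv_type_from_cn <- function(cn) {
  ifelse(cn < 2, "DEL", "DUP")
}

#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All >=1bp overlapping pairs between two interval tables (columns chrom,
# start, end; 1-based inclusive). Returns data.frame(qi, si, inter_bp) of row
# indices into a and b and the intersection width in bp.
overlap_hits <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(qi = integer(0), si = integer(0), inter_bp = numeric(0)))
  }
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ai <- which(a$chrom == chroms[k])
    bi <- which(b$chrom == chroms[k])
    ira <- IRanges::IRanges(start = a$start[ai], end = a$end[ai])
    irb <- IRanges::IRanges(start = b$start[bi], end = b$end[bi])
    h <- IRanges::findOverlaps(ira, irb)
    qi <- ai[S4Vectors::queryHits(h)]
    si <- bi[S4Vectors::subjectHits(h)]
    inter <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si]) + 1
    out[[k]] <- data.frame(qi = qi, si = si, inter_bp = as.numeric(inter))
  }
  if (length(out) == 0L) {
    return(data.frame(qi = integer(0), si = integer(0), inter_bp = numeric(0)))
  }
  do.call(rbind, out)
}

# bp covered in `calls` rows by the union of `regions` (per-call coverage of
# its own extent). Regions are reduced per chromosome first so overlapping
# region intervals are not double counted.
union_coverage_bp <- function(calls, regions) {
  cov <- numeric(nrow(calls))
  if (nrow(calls) == 0L || nrow(regions) == 0L) return(cov)
  for (chr in intersect(unique(calls$chrom), unique(regions$chrom))) {
    ci <- which(calls$chrom == chr)
    ri <- which(regions$chrom == chr)
    red <- IRanges::reduce(IRanges::IRanges(start = regions$start[ri], end = regions$end[ri]))
    irc <- IRanges::IRanges(start = calls$start[ci], end = calls$end[ci])
    h <- IRanges::findOverlaps(irc, red)
    if (length(h) == 0L) next
    qi <- S4Vectors::queryHits(h)
    inter <- pmin(calls$end[ci][qi], IRanges::end(red)[S4Vectors::subjectHits(h)]) -
      pmax(calls$start[ci][qi], IRanges::start(red)[S4Vectors::subjectHits(h)]) + 1
    tot <- tapply(as.numeric(inter), qi, sum)
    cov[ci[as.integer(names(tot))]] <- as.numeric(tot)
  }
  cov
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
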