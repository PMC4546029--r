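# Internal interval helpers.  All coordinates package-wide are 0-based
# half-open (BED convention); strand is "+", "-" or "." (unknown).

# width of the pairwise overlap of [s1,e1) with [s2,e2)
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# assert that a data.frame carries valid 0-based half-open intervals
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!nzchar(df$chrom) | is.na(df$start) | is.na(df$end) |
                 df$start < 0L | df$start >= df$end)
  if (length(bad))
    stop(sprintf("invalid %s at row %d: need non-empty chrom and 0 <= start < end",
                 what, bad[1L]))
  invisible(df)
}

# GRanges built from a chrom/start/end data.frame (0-based half-open in,
# 1-based closed inside GRanges)
as_granges <- function(df, strand = NULL) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  s <- if (is.null(strand)) "*" else ifelse(strand %in% c("+", "-"), strand, "*")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         strand = s)
}

# for each row of `a`, TRUE when it overlaps any row of `b` by >= 1 nt
overlaps_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (is.null(b) || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  out <- rep(FALSE, nrow(a))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# all (i, j) index pairs with a >= 1 nt overlap between rows of a and b
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0L || is.null(b) || nrow(b) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  data.frame(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

# deterministic ordering by (chrom, start, end)
order_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}
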