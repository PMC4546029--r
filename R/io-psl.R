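# PSL alignment format (BLAT / UCSC all_est track), 21 tab-separated columns.

PSL_COLS <- c("matches", "misMatches", "repMatches", "nCount",
              "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
              "strand", "qName", "qSize", "qStart", "qEnd",
              "tName", "tSize", "tStart", "tEnd",
              "blockCount", "blockSizes", "qStarts", "tStarts")
PSL_INT_COLS <- setdiff(PSL_COLS, c("strand", "qName", "tName",
                                    "blockSizes", "qStarts", "tStarts"))

parse_int_list <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), as.integer)
}

#' Read a PSL alignment file
#'
#' Parses a 21-column PSL file (with or without the 5-line `psLayout`
#' header) into one row per alignment.  For standard (untranslated) PSL the
#' target-side block coordinates are genome-forward regardless of the query
#' strand, so blocks need no re-orientation; the reader validates that they
#' are sorted, non-overlapping and contained in `[tStart, tEnd)`.
#' Coordinates are 0-based half-open, as in the format itself.
#'
#' @param path path to a PSL file.
#' @return A data.frame with the 21 PSL columns (comma lists kept verbatim
#'   as strings, so `write_psl()` round-trips byte-identically).
#' @seealso [write_psl()], [psl_blocks()], [psl_largest_gap()]
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  offset <- 0L
  if (length(lines) >= 1L && startsWith(lines[[1L]], "psLayout")) {
    if (length(lines) < 5L)
      stop("truncated psLayout header in ", path)
    lines <- lines[-seq_len(5L)]
    offset <- 5L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_psl())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L))
    stop(sprintf("PSL parse error at line %d: expected 21 columns, found %d",
                 which(nf != 21L)[1L] + offset, nf[nf != 21L][1L]))
  m <- matrix(unlist(fields), ncol = 21L, byrow = TRUE)
  colnames(m) <- PSL_COLS
  psl <- as.data.frame(m, stringsAsFactors = FALSE)
  for (col in PSL_INT_COLS) {
    v <- suppressWarnings(as.integer(psl[[col]]))
    if (anyNA(v))
      stop(sprintf("PSL parse error at line %d: non-numeric value '%s' in column %s",
                   which(is.na(v))[1L] + offset, psl[[col]][is.na(v)][1L], col))
    psl[[col]] <- v
  }
  validate_psl(psl, offset)
  psl
}

empty_psl <- function() {
  psl <- as.data.frame(setNames(rep(list(character(0)), 21L), PSL_COLS),
                       stringsAsFactors = FALSE)
  for (col in PSL_INT_COLS) psl[[col]] <- integer(0)
  psl
}

validate_psl <- function(psl, offset = 0L) {
  sizes <- parse_int_list(psl$blockSizes)
  tst <- parse_int_list(psl$tStarts)
  for (i in seq_len(nrow(psl))) {
    line <- i + offset
    bs <- sizes[[i]]; ts <- tst[[i]]
    if (length(bs) != psl$blockCount[i] || length(ts) != psl$blockCount[i])
      stop(sprintf("PSL parse error at line %d: blockCount %d does not match block lists",
                   line, psl$blockCount[i]))
    if (anyNA(bs) || anyNA(ts))
      stop(sprintf("PSL parse error at line %d: non-numeric block coordinate", line))
    if (any(bs <= 0L))
      stop(sprintf("PSL parse error at line %d: non-positive block size", line))
    if (is.unsorted(ts, strictly = TRUE) && length(ts) > 1L)
      stop(sprintf("PSL parse error at line %d: target blocks not sorted", line))
    if (length(ts) > 1L && any(ts[-1L] < (ts + bs)[-length(ts)]))
      stop(sprintf("PSL parse error at line %d: overlapping target blocks", line))
    if (ts[1L] < psl$tStart[i] || ts[length(ts)] + bs[length(bs)] > psl$tEnd[i])
      stop(sprintf("PSL parse error at line %d: blocks outside [tStart, tEnd)", line))
    counts <- c(psl$matches[i], psl$misMatches[i], psl$repMatches[i],
                psl$nCount[i], psl$qBaseInsert[i], psl$tBaseInsert[i])
    if (any(counts < 0L))
      stop(sprintf("PSL parse error at line %d: negative count field", line))
  }
  invisible(psl)
}

#' Write alignments back to PSL
#'
#' Emits the 21 columns tab-separated with LF line endings and no header.
#' On a data.frame produced by [read_psl()] from a headerless file the
#' output is byte-identical to the input.
#'
#' @param psl data.frame as returned by [read_psl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psl <- function(psl, path) {
  stopifnot(all(PSL_COLS %in% names(psl)))
  lines <- do.call(paste, c(lapply(PSL_COLS, function(cn) as.character(psl[[cn]])),
                            sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Per-alignment block structure
#'
#' @param psl data.frame as returned by [read_psl()].
#' @return A list with one `(start, size)` integer matrix per alignment,
#'   blocks in genome-forward order.
#' @export
psl_blocks <- function(psl) {
  sizes <- parse_int_list(psl$blockSizes)
  starts <- parse_int_list(psl$tStarts)
  Map(function(s, w) cbind(start = s, size = w), starts, sizes)
}

#' Largest single target-side gap of each alignment
#'
#' The gap between consecutive target blocks is the intron-like event used
#' by the unspliced filter: `gap_i = tStarts[i+1] - (tStarts[i] + size_i)`.
#' Single-block alignments have gap 0.
#'
#' @param psl data.frame as returned by [read_psl()].
#' @return Integer vector of largest gaps.
#' @export
psl_largest_gap <- function(psl) {
  vapply(psl_blocks(psl), function(b) {
    if (nrow(b) < 2L) return(0L)
    ends <- b[, "start"] + b[, "size"]
    max(b[-1L, "start"] - ends[-nrow(b)])
  }, integer(1))
}

#' Mismatch fraction per aligned base
#'
#' `misMatches / (matches + repMatches + misMatches)`; 0 when no bases are
#' aligned.
#'
#' @param psl data.frame as returned by [read_psl()].
#' @return Numeric vector of mismatch fractions.
#' @export
psl_mismatch_frac <- function(psl) {
  denom <- psl$matches + psl$repMatches + psl$misMatches
  ifelse(denom > 0L, psl$misMatches / denom, 0)
}

# chrom/start/end/est_id view of a PSL data.frame (target span)
psl_intervals <- function(psl) {
  data.frame(chrom = psl$tName, start = psl$tStart, end = psl$tEnd,
             est_id = psl$qName, stringsAsFactors = FALSE)
}
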