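# BED3/BED4/BED6 interval files.

#' Read a BED interval file
#'
#' @param path path to a tab-separated BED file; `track` and `#` lines are
#'   skipped.
#' @param n_fields number of fields to parse (3, 4, 5 or 6).  Fields beyond
#'   `n_fields` are ignored.
#' @return A data.frame with `chrom, start, end` plus `name` (4+),
#'   `score` (5+) and `strand` (6).
#' @export
read_bed <- function(path, n_fields = 3L) {
  stopifnot(n_fields >= 3L, n_fields <= 6L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(n_fields)]
  if (length(lines) == 0L) {
    out <- setNames(rep(list(character(0)), n_fields), cols)
    out <- as.data.frame(out, stringsAsFactors = FALSE)
    out$start <- integer(0); out$end <- integer(0)
    if ("score" %in% cols) out$score <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_fields))
    stop(sprintf("BED parse error at line %d: expected >= %d columns, found %d",
                 which(nf < n_fields)[1L], n_fields, nf[nf < n_fields][1L]))
  take <- function(k) vapply(fields, `[[`, character(1), k)
  out <- data.frame(chrom = take(1L),
                    start = suppressWarnings(as.integer(take(2L))),
                    end = suppressWarnings(as.integer(take(3L))),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop(sprintf("BED parse error at line %d: non-numeric coordinate",
                 which(is.na(out$start) | is.na(out$end))[1L]))
  if (n_fields >= 4L) out$name <- take(4L)
  if (n_fields >= 5L) out$score <- suppressWarnings(as.numeric(take(5L)))
  if (n_fields >= 6L) out$strand <- take(6L)
  validate_intervals(out, "BED record")
  out
}

#' Write intervals to BED
#'
#' Writes as many of `chrom, start, end, name, score, strand` as are
#' present (in that order), tab-separated with LF line endings.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  lines <- do.call(paste, c(lapply(cols, function(cn) as.character(df[[cn]])),
                            sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
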