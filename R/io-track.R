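# Per-base numeric tracks: bedGraph and fixed/variable-step wiggle.
# A coverage track is a data.frame (chrom, start, end, value) with sorted,
# non-overlapping intervals per chromosome, class "coverage_track".

#' Construct a coverage track
#'
#' @param df data.frame with `chrom, start, end, value`; intervals are
#'   sorted and must not overlap within a chromosome, values must be
#'   finite.
#' @return The validated, sorted data.frame with class `coverage_track`.
#' @export
coverage_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  validate_intervals(df, "coverage interval")
  if (any(!is.finite(df$value)))
    stop("coverage track values must be finite")
  df <- order_intervals(df)
  rownames(df) <- NULL
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  if (nrow(df) > 1L && any(same & df$start[-1L] < df$end[-nrow(df)]))
    stop("coverage track intervals overlap")
  class(df) <- c("coverage_track", "data.frame")
  df
}

#' Read a bedGraph track
#'
#' @param path path to a 4-column bedGraph file; `track` and `#` lines are
#'   skipped.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path) {
  df <- read_bed(path, 4L)
  names(df)[names(df) == "name"] <- "value"
  df$value <- suppressWarnings(as.numeric(df$value))
  if (anyNA(df$value))
    stop("bedGraph parse error: non-numeric value")
  coverage_track(df)
}

fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE, digits = 12)
}

#' Write a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- paste(track$chrom, track$start, track$end, fmt_num(track$value),
                 sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a wiggle track
#'
#' Supports `fixedStep` and `variableStep` declarations (1-based starts in
#' the format; converted to 0-based half-open intervals of width `span`,
#' default 1).
#'
#' @param path path to a wiggle file.
#' @return A [coverage_track()].
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  decl <- which(startsWith(lines, "fixedStep") | startsWith(lines, "variableStep"))
  if (length(lines) && (length(decl) == 0L || decl[1L] != 1L))
    stop("wiggle parse error: data line before any step declaration")
  sections <- lapply(seq_along(decl), function(k) {
    from <- decl[k] + 1L
    to <- if (k < length(decl)) decl[k + 1L] - 1L else length(lines)
    line <- lines[decl[k]]
    kv <- strsplit(strsplit(trimws(line), "[ \t]+")[[1L]][-1L], "=", fixed = TRUE)
    opts <- setNames(vapply(kv, `[[`, character(1), 2L),
                     vapply(kv, `[[`, character(1), 1L))
    if (!"chrom" %in% names(opts))
      stop(sprintf("wiggle parse error at declaration '%s': missing chrom", line))
    span <- if ("span" %in% names(opts)) as.integer(opts[["span"]]) else 1L
    body <- if (from > to) character(0) else lines[from:to]
    if (length(body) == 0L)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), value = numeric(0)))
    if (startsWith(line, "fixedStep")) {
      if (!all(c("start", "step") %in% names(opts)))
        stop("wiggle parse error: fixedStep needs start and step")
      step <- as.integer(opts[["step"]])
      start0 <- as.integer(opts[["start"]]) - 1L  # to 0-based
      v <- suppressWarnings(as.numeric(body))
      if (anyNA(v)) stop("wiggle parse error: non-numeric value")
      start <- start0 + step * (seq_along(v) - 1L)
    } else {
      f <- strsplit(trimws(body), "[ \t]+")
      if (any(lengths(f) != 2L))
        stop("wiggle parse error: variableStep needs 2 fields")
      m <- matrix(unlist(f), ncol = 2L, byrow = TRUE)
      start <- suppressWarnings(as.integer(m[, 1L])) - 1L
      v <- suppressWarnings(as.numeric(m[, 2L]))
      if (anyNA(start) || anyNA(v))
        stop("wiggle parse error: non-numeric data line")
    }
    data.frame(chrom = opts[["chrom"]], start = start, end = start + span,
               value = v, stringsAsFactors = FALSE)
  })
  df <- if (length(sections)) do.call(rbind, sections) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               value = numeric(0))
  coverage_track(df)
}

#' Write a coverage track as wiggle
#'
#' Emits `fixedStep` runs; a new declaration is started whenever the
#' interval width changes or intervals stop being contiguous, so any track
#' whose intervals share a common width round-trips through
#' [read_wiggle()].
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path) {
  out <- character(0)
  w <- track$end - track$start
  n <- nrow(track)
  new_decl <- rep(TRUE, n)
  if (n > 1L)
    new_decl[-1L] <- !(track$chrom[-1L] == track$chrom[-n] &
                         track$start[-1L] == track$end[-n] &
                         w[-1L] == w[-n])
  run <- cumsum(new_decl)
  for (r in unique(run)) {
    idx <- which(run == r)
    first <- idx[1L]
    out <- c(out,
             sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                     track$chrom[first], track$start[first] + 1L,
                     w[first], w[first]),
             fmt_num(track$value[idx]))
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}
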