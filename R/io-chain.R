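# UCSC chain format: colinear gapped pairwise genome alignments.
#
# A chain is stored as a list with the header fields and a block matrix
# `(size, dt, dq)`: `size` aligned bases, then `dt` unaligned bases on the
# source (t) genome and `dq` on the target (q) genome.  The source strand
# is always "+"; a "-" query strand means q coordinates count from the
# reversed query sequence, as in the format.

#' Read a UCSC chain file
#'
#' Validates the block arithmetic of every chain: the aligned sizes plus
#' the source-side gaps must reconstruct `tEnd - tStart` exactly, and the
#' aligned sizes plus target-side gaps must reconstruct `qEnd - qStart`.
#'
#' @param path path to a chain file.
#' @return A list of chains, each a list with `chain_id, score, t_name,
#'   t_size, t_strand, t_start, t_end, q_name, q_size, q_strand, q_start,
#'   q_end` and `blocks` (integer matrix with columns `size, dt, dq`; the
#'   last row has zero gaps).
#' @seealso [write_chain()], [lift_interval()]
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    if (!startsWith(line, "chain"))
      stop(sprintf("chain parse error at line %d: expected 'chain' header", i))
    h <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(h) != 13L)
      stop(sprintf("chain parse error at line %d: header needs 13 fields", i))
    ch <- list(score = as.numeric(h[2L]),
               t_name = h[3L], t_size = as.integer(h[4L]), t_strand = h[5L],
               t_start = as.integer(h[6L]), t_end = as.integer(h[7L]),
               q_name = h[8L], q_size = as.integer(h[9L]), q_strand = h[10L],
               q_start = as.integer(h[11L]), q_end = as.integer(h[12L]),
               chain_id = h[13L])
    if (ch$t_strand != "+")
      stop(sprintf("chain %s: source strand must be '+'", ch$chain_id))
    if (!ch$q_strand %in% c("+", "-"))
      stop(sprintf("chain %s: query strand must be '+' or '-'", ch$chain_id))
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > length(lines))
        stop(sprintf("chain %s: truncated block list", ch$chain_id))
      b <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
      v <- suppressWarnings(as.integer(b))
      if (anyNA(v))
        stop(sprintf("chain parse error at line %d: non-numeric block", i))
      if (length(v) == 1L) {
        blocks[[length(blocks) + 1L]] <- c(v, 0L, 0L)
        i <- i + 1L
        break
      }
      if (length(v) != 3L)
        stop(sprintf("chain parse error at line %d: block needs 1 or 3 fields", i))
      blocks[[length(blocks) + 1L]] <- v
      i <- i + 1L
    }
    ch$blocks <- do.call(rbind, blocks)
    colnames(ch$blocks) <- c("size", "dt", "dq")
    if (any(ch$blocks[, "size"] <= 0L) || any(ch$blocks[, c("dt", "dq")] < 0L))
      stop(sprintf("chain %s: block sizes must be positive, gaps non-negative",
                   ch$chain_id))
    if (sum(ch$blocks[, "size"]) + sum(ch$blocks[, "dt"]) != ch$t_end - ch$t_start ||
        sum(ch$blocks[, "size"]) + sum(ch$blocks[, "dq"]) != ch$q_end - ch$q_start)
      stop(sprintf("chain %s: block arithmetic does not reconstruct the declared spans",
                   ch$chain_id))
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write chains to a UCSC chain file
#'
#' @param chains list of chains as returned by [read_chain()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    out <- c(out, paste("chain",
                        format(ch$score, scientific = FALSE, trim = TRUE),
                        ch$t_name, ch$t_size, ch$t_strand, ch$t_start, ch$t_end,
                        ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                        ch$chain_id))
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      out <- c(out, paste(b[-n, "size"], b[-n, "dt"], b[-n, "dq"]))
    out <- c(out, as.character(b[n, "size"]), "")
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}
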