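# Chain-based coordinate lifting and cross-species cluster pairing.

#' Lift an interval through chain alignments
#'
#' Maps each base of the interval that falls into an aligned chain block
#' by its block offset and returns the hull of the mapped bases on the
#' target genome (minus-strand chains are reported in forward coordinates
#' of the target).  The lift fails (`NULL`) when the fraction of mapped
#' bases on the best chain is below `min_mapped_frac`, or when more than
#' one chain maps the interval above that threshold (ambiguous placement,
#' the classic "multiple output regions" rejection).
#'
#' @param interval a list/row with `chrom, start, end`.
#' @param chains chain list from [read_chain()].
#' @param min_mapped_frac minimum mapped-base fraction in (0, 1].
#' @return A list `(chrom, start, end, mapped_frac, chain_id)` or `NULL`
#'   when the interval is unmappable.
#' @examples
#' ch <- list(list(chain_id = "1", score = 1000, t_name = "chr1",
#'                 t_size = 1000L, t_strand = "+", t_start = 0L, t_end = 1000L,
#'                 q_name = "chr1", q_size = 1000L, q_strand = "+",
#'                 q_start = 0L, q_end = 1000L,
#'                 blocks = cbind(size = 1000L, dt = 0L, dq = 0L)))
#' lift_interval(list(chrom = "chr1", start = 100, end = 200), ch)
#' @export
lift_interval <- function(interval, chains, min_mapped_frac = 0.95) {
  stopifnot(min_mapped_frac > 0, min_mapped_frac <= 1)
  width <- interval$end - interval$start
  results <- list()
  for (ch in chains) {
    if (ch$t_name != interval$chrom) next
    if (ch$t_end <= interval$start || ch$t_start >= interval$end) next
    t_pos <- ch$t_start
    q_pos <- ch$q_start
    mapped <- 0L
    q_lo <- NA_integer_; q_hi <- NA_integer_
    b <- ch$blocks
    for (k in seq_len(nrow(b))) {
      size <- b[k, "size"]
      os <- max(interval$start, t_pos)
      oe <- min(interval$end, t_pos + size)
      if (oe > os) {
        qs <- q_pos + (os - t_pos)
        qe <- q_pos + (oe - t_pos)
        mapped <- mapped + (oe - os)
        q_lo <- min(q_lo, qs, na.rm = TRUE)
        q_hi <- max(q_hi, qe, na.rm = TRUE)
      }
      t_pos <- t_pos + size + b[k, "dt"]
      q_pos <- q_pos + size + b[k, "dq"]
      if (t_pos >= interval$end) break
    }
    if (mapped == 0L) next
    if (ch$q_strand == "-") {
      tmp <- q_lo
      q_lo <- ch$q_size - q_hi
      q_hi <- ch$q_size - tmp
    }
    results[[length(results) + 1L]] <- list(
      chrom = ch$q_name, start = q_lo, end = q_hi,
      mapped_frac = mapped / width, chain_id = ch$chain_id)
  }
  ok <- Filter(function(r) r$mapped_frac >= min_mapped_frac, results)
  if (length(ok) != 1L) return(NULL)
  ok[[1L]]
}

#' Lift a set of intervals
#'
#' Vectorised driver over [lift_interval()].
#'
#' @param df data.frame with `chrom, start, end`.
#' @param chains chain list from [read_chain()].
#' @param min_mapped_frac see [lift_interval()].
#' @return A data.frame with `chrom, start, end, mapped_frac, chain_id`
#'   (NA rows for unmappable intervals), row-parallel to `df`.
#' @export
lift_intervals <- function(df, chains, min_mapped_frac = 0.95) {
  out <- data.frame(chrom = rep(NA_character_, nrow(df)),
                    start = NA_integer_, end = NA_integer_,
                    mapped_frac = NA_real_, chain_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    r <- lift_interval(list(chrom = df$chrom[i], start = df$start[i],
                            end = df$end[i]), chains, min_mapped_frac)
    if (!is.null(r)) out[i, ] <- r[c("chrom", "start", "end", "mapped_frac",
                                     "chain_id")]
  }
  out
}

#' Pair orthologous clusters across two genomes
#'
#' Lifts every genome-A cluster to genome B and pairs it with every B
#' cluster its image overlaps by at least 1 nt; then symmetrically lifts B
#' clusters to A; the two directional pair sets are combined (a pair found
#' by either run counts) and flagged `A->B`, `B->A` or `both`.  When the
#' clusters carry a `class` column, pairs between clusters of the same
#' class are flagged.
#'
#' @param clusters_a,clusters_b cluster data.frames (from
#'   [cluster_ests()], optionally classified).
#' @param chains_ab chains with genome A as source, B as target.
#' @param chains_ba chains with genome B as source, A as target.
#' @param min_mapped_frac see [lift_interval()].
#' @return A data.frame of pairs: `cluster_a, cluster_b, detected_by,
#'   same_class` (NA when classes are unavailable).
#' @export
pair_orthologs <- function(clusters_a, clusters_b, chains_ab, chains_ba,
                           min_mapped_frac = 0.95) {
  direction <- function(src, dst, chains) {
    lifted <- lift_intervals(src[, c("chrom", "start", "end")], chains,
                             min_mapped_frac)
    keep <- which(!is.na(lifted$start))
    if (length(keep) == 0L)
      return(data.frame(src = character(0), dst = character(0)))
    hits <- overlap_pairs(lifted[keep, c("chrom", "start", "end")],
                          dst[, c("chrom", "start", "end")])
    data.frame(src = src$cluster_id[keep][hits$a],
               dst = dst$cluster_id[hits$b], stringsAsFactors = FALSE)
  }
  ab <- direction(clusters_a, clusters_b, chains_ab)
  ba <- direction(clusters_b, clusters_a, chains_ba)
  key_ab <- paste(ab$src, ab$dst)
  key_ba <- paste(ba$dst, ba$src)
  all_keys <- union(key_ab, key_ba)
  pairs <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  out <- if (length(all_keys)) {
    data.frame(cluster_a = pairs[, 1L], cluster_b = pairs[, 2L],
               detected_by = ifelse(all_keys %in% key_ab & all_keys %in% key_ba,
                                    "both",
                                    ifelse(all_keys %in% key_ab, "A->B", "B->A")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cluster_a = character(0), cluster_b = character(0),
               detected_by = character(0), stringsAsFactors = FALSE)
  }
  if ("class" %in% names(clusters_a) && "class" %in% names(clusters_b)) {
    ca <- setNames(clusters_a$class, clusters_a$cluster_id)
    cb <- setNames(clusters_b$class, clusters_b$cluster_id)
    out$same_class <- unname(ca[out$cluster_a] == cb[out$cluster_b])
  } else {
    out$same_class <- NA
  }
  out <- out[order(out$cluster_a, out$cluster_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise an ortholog pair set
#'
#' @param pairs data.frame from [pair_orthologs()].
#' @param clusters_a,clusters_b the full cluster sets of the two genomes.
#' @return Named integer vector: `n_pairs`, `n_distinct_a`,
#'   `n_distinct_b`, `n_same_class`, `n_unpaired_a`, `n_unpaired_b`.
#' @export
conservation_summary <- function(pairs, clusters_a, clusters_b) {
  c(n_pairs = nrow(pairs),
    n_distinct_a = length(unique(pairs$cluster_a)),
    n_distinct_b = length(unique(pairs$cluster_b)),
    n_same_class = sum(pairs$same_class, na.rm = TRUE),
    n_unpaired_a = nrow(clusters_a) - length(unique(pairs$cluster_a)),
    n_unpaired_b = nrow(clusters_b) - length(unique(pairs$cluster_b)))
}
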