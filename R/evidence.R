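# Orthogonal evidence overlays: CAGE TSS orientation, per-cell expression
# breadth, chromatin-state support, RNA-seq read support.

CHROMATIN_STATES <- c("TSS", "PF", "E", "WE", "CTCF", "T", "R")

#' Orient clusters by CAGE TSS peaks
#'
#' EST clusters are unstranded; stranded CAGE TSS peaks near a cluster end
#' reveal the reading direction.  A cluster has forward evidence when a
#' `+`-strand peak overlaps its first `cage_window_nt` (84) nucleotides by
#' at least 1 nt, and reverse evidence when a `-`-strand peak overlaps its
#' last 84 nucleotides.  Forward-only evidence gives `forward`,
#' reverse-only gives `reverse`, both give `bidirectional` (likely
#' bidirectionally transcribed loci, disregarded downstream), neither
#' gives `none`.  Windows are clipped to the cluster for clusters shorter
#' than the window.
#'
#' @param clusters data.frame with `chrom, start, end`.
#' @param peaks stranded peak data.frame (`chrom, start, end, strand`,
#'   e.g. from [read_bed()] with `n_fields = 6`).
#' @param config a [uest_config()].
#' @return Character vector, one of `forward, reverse, bidirectional,
#'   none` per cluster.
#' @export
orient_by_cage <- function(clusters, peaks, config = uest_config()) {
  n <- nrow(clusters)
  if (n == 0L) return(character(0))
  w <- config$cage_window_nt
  fw_win <- data.frame(chrom = clusters$chrom, start = clusters$start,
                       end = pmin(clusters$end, clusters$start + w))
  rv_win <- data.frame(chrom = clusters$chrom,
                       start = pmax(clusters$start, clusters$end - w),
                       end = clusters$end)
  fw_peaks <- peaks[peaks$strand == "+", , drop = FALSE]
  rv_peaks <- peaks[peaks$strand == "-", , drop = FALSE]
  fw <- overlaps_any(fw_win, fw_peaks)
  rv <- overlaps_any(rv_win, rv_peaks)
  ifelse(fw & rv, "bidirectional",
         ifelse(fw, "forward", ifelse(rv, "reverse", "none")))
}

#' Expression breadth across cell types
#'
#' Runs [orient_by_cage()] once per cell-type peak set and counts, per
#' cluster, the cell types in which the cluster has an unambiguous
#' orientation (`forward` or `reverse`; `bidirectional` and `none` do not
#' count).
#'
#' @param clusters data.frame with `chrom, start, end`.
#' @param peak_sets named list of per-cell-type peak data.frames.
#' @param config a [uest_config()].
#' @return A list with `breadth` (integer per cluster) and `histogram`
#'   (table of breadth values over clusters with breadth >= 1).
#' @export
cell_breadth <- function(clusters, peak_sets, config = uest_config()) {
  counts <- rep(0L, nrow(clusters))
  for (peaks in peak_sets) {
    o <- orient_by_cage(clusters, peaks, config)
    counts <- counts + (o %in% c("forward", "reverse"))
  }
  list(breadth = counts, histogram = table(counts[counts >= 1L]))
}

#' Chromatin-state support per cluster
#'
#' Segmentations label every genomic position with one of seven chromatin
#' states (`TSS` promoter, `PF` promoter-flanking, `E` enhancer, `WE` weak
#' enhancer/open chromatin, `CTCF`, `T` transcribed, `R` repressed/low
#' activity).  Cell lines are taken together: a cluster has TSS-state
#' (resp. transcribed-state) support when a `TSS` (resp. `T`) segment from
#' *any* cell line overlaps it by at least 1 nt.
#'
#' @param clusters data.frame with `cluster_id, chrom, start, end`.
#' @param segments segmentation data.frame (`chrom, start, end, state`;
#'   the `name` column of a BED4 file is accepted as the state).
#' @return A data.frame per cluster: `cluster_id, has_TSS_state,
#'   has_T_state, states` (comma-separated multiset of overlapped states).
#' @export
chromatin_support <- function(clusters, segments) {
  if (!"state" %in% names(segments) && "name" %in% names(segments))
    segments$state <- segments$name
  bad <- setdiff(unique(segments$state), CHROMATIN_STATES)
  if (length(bad)) stop("unknown chromatin state label: ", bad[1L])
  hits <- overlap_pairs(clusters[, c("chrom", "start", "end")],
                        segments[, c("chrom", "start", "end")])
  states_by_cluster <- split(segments$state[hits$b], hits$a)
  states <- character(nrow(clusters))
  idx <- as.integer(names(states_by_cluster))
  states[idx] <- vapply(states_by_cluster, function(s)
    paste(sort(s), collapse = ","), character(1))
  data.frame(cluster_id = clusters$cluster_id,
             has_TSS_state = vapply(strsplit(states, ","), function(s)
               "TSS" %in% s, logical(1)),
             has_T_state = vapply(strsplit(states, ","), function(s)
               "T" %in% s, logical(1)),
             states = states, stringsAsFactors = FALSE)
}

#' RNA-seq read support per cluster
#'
#' A cluster is supported when, in at least one library, the summed read
#' count of bedGraph intervals intersecting the cluster (by >= 1 nt)
#' reaches `min_rnaseq_reads`.  The threshold is per library; counts are
#' never summed across libraries.
#'
#' @param clusters data.frame with `chrom, start, end`.
#' @param coverage_tracks one [coverage_track()] or a list of them, one
#'   per library, values interpreted as read counts per interval.
#' @param config a [uest_config()].
#' @return Logical vector per cluster.
#' @export
rnaseq_support <- function(clusters, coverage_tracks, config = uest_config()) {
  if (inherits(coverage_tracks, "coverage_track"))
    coverage_tracks <- list(coverage_tracks)
  supported <- rep(FALSE, nrow(clusters))
  for (track in coverage_tracks) {
    hits <- overlap_pairs(clusters[, c("chrom", "start", "end")],
                          track[, c("chrom", "start", "end")])
    sums <- vapply(split(track$value[hits$b], hits$a), sum, numeric(1))
    idx <- as.integer(names(sums))
    supported[idx] <- supported[idx] | sums >= config$min_rnaseq_reads
  }
  supported
}

#' Assemble the per-cluster evidence matrix
#'
#' Combines orientation, chromatin and RNA-seq evidence with two derived
#' columns: `refseq_tss` flags clusters that overlap any 5'UTR (>= 1 nt)
#' or lie completely within an upstream flank -- their TSS signal cannot
#' be told apart from the host gene's own, so they are excluded from
#' sense/antisense accounting; `rel_orientation` compares the CAGE
#' orientation with the host-gene strand (`sense`/`antisense`,
#' `ambiguous` for bidirectional clusters, `NA` without orientation, a
#' unique host strand, or for `refseq_tss` clusters).
#'
#' @param clusters classified clusters ([classify_clusters()] output).
#' @param genes gene models from [read_genepred()].
#' @param components [build_components()] table (built when `NULL`).
#' @param peaks optional CAGE peaks (BED6 data.frame).
#' @param segments optional chromatin segmentation (see
#'   [chromatin_support()]).
#' @param coverage_tracks optional RNA-seq [coverage_track()] list.
#' @param config a [uest_config()].
#' @return A data.frame keyed by `cluster_id` with the available evidence
#'   columns.
#' @export
evidence_matrix <- function(clusters, genes, components = NULL, peaks = NULL,
                            segments = NULL, coverage_tracks = NULL,
                            config = uest_config()) {
  if (is.null(components)) components <- build_components(genes, config = config)
  out <- data.frame(cluster_id = clusters$cluster_id,
                    class = clusters$class, stringsAsFactors = FALSE)
  utr5s <- components[components$type == "utr5", , drop = FALSE]
  ups <- components[components$type == "upstream", , drop = FALSE]
  hits_up <- overlap_pairs(clusters[, c("chrom", "start", "end")], ups)
  contained <- hits_up[clusters$start[hits_up$a] >= ups$start[hits_up$b] &
                         clusters$end[hits_up$a] <= ups$end[hits_up$b], ,
                       drop = FALSE]
  out$refseq_tss <- overlaps_any(clusters[, c("chrom", "start", "end")], utr5s) |
    seq_len(nrow(clusters)) %in% contained$a
  if (!is.null(peaks)) {
    out$orientation <- orient_by_cage(clusters, peaks, config)
    strand_by_gene <- setNames(genes$strand, genes$gene_id)
    host <- vapply(strsplit(clusters$genes, ",", fixed = TRUE), function(g) {
      s <- unique(strand_by_gene[g[nzchar(g)]])
      if (length(s) == 1L && !is.na(s)) s else NA_character_
    }, character(1))
    ori_strand <- c(forward = "+", reverse = "-")[out$orientation]
    out$rel_orientation <- ifelse(
      out$refseq_tss | is.na(host), NA_character_,
      ifelse(out$orientation == "bidirectional", "ambiguous",
             ifelse(is.na(ori_strand), NA_character_,
                    ifelse(ori_strand == host, "sense", "antisense"))))
  }
  if (!is.null(segments)) {
    chrom <- chromatin_support(clusters, segments)
    out$has_TSS_state <- chrom$has_TSS_state
    out$has_T_state <- chrom$has_T_state
  }
  if (!is.null(coverage_tracks))
    out$rnaseq_supported <- rnaseq_support(clusters, coverage_tracks, config)
  out
}
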