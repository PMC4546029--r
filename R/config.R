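#' Pipeline parameters
#'
#' Bundles every numeric parameter of the analysis in one place.  The
#' defaults are the constants used throughout: an alignment is "unspliced"
#' when its largest genomic gap is at most 30 nt (smaller introns are
#' extremely rare), alignments with more than 5 % mismatched bases are
#' discarded, a cluster needs at least 3 member ESTs, ESTs separated by at
#' most 30 nt are merged, gene vicinity means within 5 kb of the transcript
#' ends, a gene component counts as overlapped only above 20 nt, CAGE
#' orientation windows are 84 nt from either cluster end, and RNA-seq
#' support requires at least 10 reads in at least one library.
#'
#' @param max_gap_nt maximum single genomic (target-side) gap, in nt, for an
#'   alignment to count as unspliced.
#' @param max_mismatch_frac maximum mismatch fraction, per aligned base
#'   (`misMatches / (matches + repMatches + misMatches)`).
#' @param min_cluster_size minimum number of member ESTs per cluster.
#' @param cluster_join_nt two ESTs separated by at most this many nt join
#'   the same cluster (overlap counts as separation 0).
#' @param flank_nt length of the upstream/downstream flank attached to each
#'   gene, in nt.
#' @param min_component_overlap_nt a cluster/gene-component overlap must be
#'   strictly greater than this to be considered by the classifier.
#' @param cage_window_nt length of the CAGE orientation window at each
#'   cluster end.
#' @param min_rnaseq_reads minimum summed read count, within a single
#'   library, for RNA-seq support.
#' @param min_mapped_frac minimum fraction of interval bases that must map
#'   through a single chain for coordinate lifting to succeed.
#' @param gap_mode `"largest"` applies `max_gap_nt` to the largest single
#'   target-side gap (intron-like event); `"summed"` applies it to the sum
#'   of all target-side inserted bases.
#' @return An object of class `uest_config` (a validated list).
#' @examples
#' cfg <- uest_config()
#' cfg$max_gap_nt
#' @export
uest_config <- function(max_gap_nt = 30L,
                        max_mismatch_frac = 0.05,
                        min_cluster_size = 3L,
                        cluster_join_nt = 30L,
                        flank_nt = 5000L,
                        min_component_overlap_nt = 20L,
                        cage_window_nt = 84L,
                        min_rnaseq_reads = 10L,
                        min_mapped_frac = 0.95,
                        gap_mode = c("largest", "summed")) {
  gap_mode <- match.arg(gap_mode)
  cfg <- list(
    max_gap_nt = as.integer(max_gap_nt),
    max_mismatch_frac = as.numeric(max_mismatch_frac),
    min_cluster_size = as.integer(min_cluster_size),
    cluster_join_nt = as.integer(cluster_join_nt),
    flank_nt = as.integer(flank_nt),
    min_component_overlap_nt = as.integer(min_component_overlap_nt),
    cage_window_nt = as.integer(cage_window_nt),
    min_rnaseq_reads = as.integer(min_rnaseq_reads),
    min_mapped_frac = as.numeric(min_mapped_frac),
    gap_mode = gap_mode
  )
  num <- cfg[setdiff(names(cfg), "gap_mode")]
  if (any(vapply(num, function(x) !is.finite(x) || x <= 0, logical(1))))
    stop("all uest_config parameters must be positive and finite")
  if (cfg$max_mismatch_frac >= 1)
    stop("max_mismatch_frac must be in (0, 1)")
  if (cfg$min_mapped_frac > 1)
    stop("min_mapped_frac must be in (0, 1]")
  structure(cfg, class = "uest_config")
}

#' @export
print.uest_config <- function(x, ...) {
  cat("uEST pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
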