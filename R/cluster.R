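# Merging unspliced ESTs into clusters.

#' Merge unspliced ESTs into clusters
#'
#' Two ESTs on the same chromosome belong to the same cluster when they
#' overlap or are separated by at most `cluster_join_nt` nucleotides
#' (`gap = max(0, later.start - earlier.end)`; in half-open coordinates an
#' EST ending at 100 and one starting at 130 have gap 30 and are joined,
#' start 131 gives gap 31 and is not joined).  Clusters are the connected
#' components of this relation, computed by a sorted sweep per chromosome;
#' strand is ignored because EST reading direction is generally unknown.
#' Components with fewer than `min_cluster_size` members are discarded.
#'
#' @param ests either a PSL data.frame (from [read_psl()], typically after
#'   [filter_unspliced()]) or a data.frame with `chrom, start, end, est_id`.
#' @param config a [uest_config()].
#' @param report optional `uest_funnel` from [filter_unspliced()]; when
#'   given, its `clusters` entry is filled in and the updated report is
#'   attached as attribute `"report"` of the result.
#' @return A data.frame of clusters sorted by `(chrom, start)` with columns
#'   `cluster_id` (deterministic, `uc` + zero-padded rank), `chrom, start,
#'   end` (the union hull of the members), `n_members` and `members`
#'   (comma-separated EST ids).
#' @examples
#' ests <- data.frame(chrom = "chr1", start = c(0, 120, 220),
#'                    end = c(100, 200, 300),
#'                    est_id = c("a", "b", "c"))
#' cluster_ests(ests)  # gaps of 20 nt: one cluster spanning [0, 300)
#' @export
cluster_ests <- function(ests, config = uest_config(), report = NULL) {
  if ("tName" %in% names(ests)) ests <- psl_intervals(ests)
  stopifnot(all(c("chrom", "start", "end", "est_id") %in% names(ests)))
  ests <- ests[order(ests$chrom, ests$start, ests$end, ests$est_id), ,
               drop = FALSE]
  out <- list()
  for (chr in unique(ests$chrom)) {
    e <- ests[ests$chrom == chr, , drop = FALSE]
    # sweep: a new component starts where the running max end leaves a gap
    # larger than the join distance
    run_end <- cummax(e$end)
    new_comp <- c(TRUE, e$start[-1L] > run_end[-nrow(e)] + config$cluster_join_nt)
    comp <- cumsum(new_comp)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      if (length(idx) < config$min_cluster_size) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(e$start[idx]), end = max(e$end[idx]),
        n_members = length(idx),
        members = paste(e$est_id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_members = integer(0), members = character(0),
               stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  clusters <- cbind(cluster_id = sprintf("uc%05d", seq_len(nrow(clusters))),
                    clusters, stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  if (!is.null(report)) {
    report["clusters"] <- nrow(clusters)
    attr(clusters, "report") <- report
  }
  clusters
}

#' Write clusters as BED6
#'
#' `name` is the cluster id, `score` the member count, strand is `"."`
#' (EST clusters are unstranded at creation).
#'
#' @param clusters data.frame from [cluster_ests()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  write_bed(data.frame(chrom = clusters$chrom, start = clusters$start,
                       end = clusters$end, name = clusters$cluster_id,
                       score = clusters$n_members, strand = ".",
                       stringsAsFactors = FALSE), path)
}
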