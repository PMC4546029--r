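# Per-cluster and per-class conservation-score summaries over a per-base
# score track (phastCons semantics: values in [0, 1], posterior
# probabilities of negative selection).

#' Mean track score over intervals
#'
#' The mean is taken over the *scored* bases only: `sum(value x covered
#' length) / sum(covered length)`; bases with no track coverage do not
#' enter the denominator (they are not imputed as 0).  Intervals with zero
#' scored bases yield `NA`.
#'
#' @param intervals data.frame with `chrom, start, end` (one row per
#'   interval).
#' @param track a [coverage_track()]; values outside `[0, 1]` raise a
#'   validation warning (real tracks contain rounding slop) but are used
#'   as-is.
#' @return A data.frame row-parallel to `intervals` with `mean` (NA when
#'   unscored) and `n_scored` (scored base count).
#' @examples
#' trk <- coverage_track(data.frame(chrom = "chr1", start = c(0, 10),
#'                                  end = c(10, 20), value = c(0.2, 0.8)))
#' mean_score(data.frame(chrom = "chr1", start = 0, end = 20), trk)
#' @export
mean_score <- function(intervals, track) {
  if (any(track$value < 0 | track$value > 1))
    warning("coverage track has values outside [0, 1]")
  hits <- overlap_pairs(intervals[, c("chrom", "start", "end")],
                        track[, c("chrom", "start", "end")])
  w <- overlap_width(intervals$start[hits$a], intervals$end[hits$a],
                     track$start[hits$b], track$end[hits$b])
  num <- rep(0, nrow(intervals))
  den <- rep(0, nrow(intervals))
  if (nrow(hits)) {
    sums <- rowsum(cbind(w * track$value[hits$b], w), hits$a)
    idx <- as.integer(rownames(sums))
    num[idx] <- sums[, 1L]
    den[idx] <- sums[, 2L]
  }
  data.frame(mean = ifelse(den > 0, num / den, NA_real_),
             n_scored = as.integer(den))
}

#' Per-class conservation table
#'
#' For every cluster class the mean over clusters of the per-cluster mean
#' score (clusters without scored bases are excluded), followed by the
#' supplied background sets (summarised the same way, one mean per
#' background interval) and an `AVG` row: the *unweighted* mean of the
#' class means over the real classes (`NO_CLASS` excluded).  `TEX`
#' clusters are optionally subdivided by their CDS overlap into
#' `TEX_cds` (fully inside coding exonic sequence), `TEX_partial_cds` and
#' `TEX_noncds`.  IGR clusters overlapping a supplied coding-signal hit
#' list are dropped before averaging.
#'
#' @param clusters classified clusters ([classify_clusters()] output).
#' @param track a [coverage_track()] of conservation scores.
#' @param backgrounds named list of interval data.frames (e.g. introns,
#'   exons, genome windows).
#' @param cds_exonic optional data.frame of coding exonic intervals for
#'   the TEX subdivision.
#' @param coding_hits optional data.frame of intervals with significant
#'   protein-coding signal; IGR clusters overlapping one are excluded.
#' @return A data.frame `set, mean_score, n` with one row per class,
#'   TEX subclass, background and the `AVG` row.
#' @export
class_conservation <- function(clusters, track, backgrounds = list(),
                               cds_exonic = NULL, coding_hits = NULL) {
  if (!is.null(coding_hits) && nrow(coding_hits) > 0L) {
    drop <- clusters$class == "IGR" &
      overlaps_any(clusters[, c("chrom", "start", "end")], coding_hits)
    clusters <- clusters[!drop, , drop = FALSE]
  }
  per_cluster <- mean_score(clusters, track)
  rows <- list()
  class_means <- c()
  for (cl in CLUSTER_CLASSES) {
    m <- per_cluster$mean[clusters$class == cl & !is.na(per_cluster$mean)]
    rows[[cl]] <- data.frame(set = cl, mean_score = mean(m), n = length(m))
    if (cl != "NO_CLASS") class_means[cl] <- mean(m)
  }
  rows[["AVG"]] <- data.frame(set = "AVG",
                              mean_score = mean(class_means, na.rm = TRUE),
                              n = sum(!is.na(class_means)))
  if (!is.null(cds_exonic)) {
    tex <- clusters$class == "TEX"
    hits <- overlap_pairs(clusters[, c("chrom", "start", "end")], cds_exonic)
    covered <- rep(0L, nrow(clusters))
    if (nrow(hits)) {
      w <- overlap_width(clusters$start[hits$a], clusters$end[hits$a],
                         cds_exonic$start[hits$b], cds_exonic$end[hits$b])
      agg <- rowsum(w, hits$a)
      covered[as.integer(rownames(agg))] <- agg[, 1L]
    }
    width <- clusters$end - clusters$start
    sub <- ifelse(covered == width, "TEX_cds",
                  ifelse(covered > 0L, "TEX_partial_cds", "TEX_noncds"))
    for (s in c("TEX_cds", "TEX_partial_cds", "TEX_noncds")) {
      m <- per_cluster$mean[tex & sub == s & !is.na(per_cluster$mean)]
      rows[[s]] <- data.frame(set = s, mean_score = mean(m), n = length(m))
    }
  }
  for (nm in names(backgrounds)) {
    bg <- mean_score(backgrounds[[nm]], track)
    m <- bg$mean[!is.na(bg$mean)]
    rows[[paste0("bg_", nm)]] <- data.frame(set = paste0("bg_", nm),
                                            mean_score = mean(m), n = length(m))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
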