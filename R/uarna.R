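# 3'UTR-associated RNA (uaRNA) candidate calling.

#' Call uaRNA candidates
#'
#' A uaRNA is an independent transcript living in the 3'UTR territory of a
#' host gene.  A cluster is a candidate when (a) it overlaps the 3'UTR of
#' at least one in-range gene by more than `min_component_overlap_nt`,
#' (b) it overlaps no in-range gene's 5'UTR above the same threshold
#' (applied to *all* in-range genes -- the strict reading), and (c) it has
#' its own TSS evidence: with `evidence = "cage"`, an unambiguous
#' [orient_by_cage()] orientation (`forward` or `reverse`, i.e. a stranded
#' TSS peak in the 84-nt end window); with `evidence = "chromatin"`, a
#' >= 1 nt overlap with a TSS-state segment.  5'-side uaRNAs are not
#' called: at the 5' end the host gene's own TSS cannot be told apart
#' from that of an embedded transcript.
#'
#' @param clusters classified clusters ([classify_clusters()] output).
#' @param genes gene models from [read_genepred()].
#' @param evidence `"cage"` or `"chromatin"`.
#' @param peaks CAGE peaks (required for `evidence = "cage"`).
#' @param segments chromatin segmentation (required for
#'   `evidence = "chromatin"`; only `TSS`-state segments are used).
#' @param components optional precomputed [build_components()] table.
#' @param config a [uest_config()].
#' @return A data.frame of candidates: `cluster_id, host_genes`
#'   (comma-separated genes whose 3'UTR is overlapped), `evidence`,
#'   `orientation` (CAGE orientation, `NA` for chromatin calls).
#' @export
call_uarnas <- function(clusters, genes, evidence = c("cage", "chromatin"),
                        peaks = NULL, segments = NULL, components = NULL,
                        config = uest_config()) {
  evidence <- match.arg(evidence)
  if (is.null(components)) components <- build_components(genes, config = config)
  thr <- config$min_component_overlap_nt
  in_range <- genes_in_range(clusters, genes, config)
  utr3 <- components[components$type == "utr3", , drop = FALSE]
  utr5 <- components[components$type == "utr5", , drop = FALSE]

  over_thr <- function(parts) {
    hits <- overlap_pairs(clusters[, c("chrom", "start", "end")], parts)
    if (nrow(hits) == 0L) return(hits)
    w <- overlap_width(clusters$start[hits$a], clusters$end[hits$a],
                       parts$start[hits$b], parts$end[hits$b])
    # only count in-range genes
    key <- paste(clusters$cluster_id[hits$a], parts$gene_id[hits$b])
    ok <- w > thr & key %in% paste(in_range$cluster_id, in_range$gene_id)
    hits[ok, , drop = FALSE]
  }
  h3 <- over_thr(utr3)
  h5 <- over_thr(utr5)
  cand <- rep(FALSE, nrow(clusters))
  cand[unique(h3$a)] <- TRUE
  cand[unique(h5$a)] <- FALSE

  orientation <- rep(NA_character_, nrow(clusters))
  if (evidence == "cage") {
    if (is.null(peaks)) stop("evidence = 'cage' requires peaks")
    orientation <- orient_by_cage(clusters, peaks, config)
    cand <- cand & orientation %in% c("forward", "reverse")
  } else {
    if (is.null(segments)) stop("evidence = 'chromatin' requires segments")
    if (!"state" %in% names(segments) && "name" %in% names(segments))
      segments$state <- segments$name
    tss <- segments[segments$state == "TSS", , drop = FALSE]
    cand <- cand & overlaps_any(clusters[, c("chrom", "start", "end")], tss)
  }
  hosts <- vapply(seq_len(nrow(clusters)), function(i) {
    g <- unique(utr3$gene_id[h3$b[h3$a == i]])
    paste(sort(g), collapse = ",")
  }, character(1))
  out <- data.frame(cluster_id = clusters$cluster_id[cand],
                    host_genes = hosts[cand],
                    evidence = rep(evidence, sum(cand)),
                    orientation = orientation[cand],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersect CAGE-based and chromatin-based uaRNA calls
#'
#' @param cage_calls,chromatin_calls data.frames from [call_uarnas()] (or
#'   anything with a `cluster_id` column).
#' @return A list of cluster-id vectors `cage_only`, `chromatin_only`,
#'   `both`.
#' @export
intersect_calls <- function(cage_calls, chromatin_calls) {
  a <- unique(cage_calls$cluster_id)
  b <- unique(chromatin_calls$cluster_id)
  list(cage_only = sort(setdiff(a, b)),
       chromatin_only = sort(setdiff(b, a)),
       both = sort(intersect(a, b)))
}
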