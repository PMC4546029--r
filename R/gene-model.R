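# Decomposition of gene models into the labeled components the classifier
# consumes: exons, introns, exonic 5'/3'UTR pieces, upstream and downstream
# flanks, all strand-aware.

COMPONENT_TYPES <- c("exon", "intron", "utr5", "utr3", "upstream", "downstream")

#' Decompose gene models into labeled components
#'
#' For every transcript the exons are taken as given (genomic order,
#' instance-numbered left to right), introns are exactly the gaps between
#' consecutive exons, the 5'/3'UTRs are the *exonic* bases between the
#' transcript ends and the CDS (5' is leftmost on `+` genes and rightmost
#' on `-` genes; non-coding transcripts, `cdsStart == cdsEnd`, have no
#' UTRs), and a flank of `flank_nt` is attached on each side: the upstream
#' flank abuts the transcription start (txStart on `+`, txEnd on `-`).
#' Flanks are clipped to `[0, chrom_size]`.
#'
#' Overlapping isoforms are decomposed independently; conflicts between
#' their classifications are resolved later by [classify_clusters()].
#'
#' @param genes gene models from [read_genepred()].
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   clip flanks on the right.
#' @param config a [uest_config()].
#' @return A data.frame with one row per component instance: `gene_id,
#'   chrom, strand, type` (one of `exon, intron, utr5, utr3, upstream,
#'   downstream`), `instance` (genomic left-to-right index within type)
#'   and `start, end`.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                 tx_start = 100L, tx_end = 400L,
#'                 cds_start = 150L, cds_end = 350L, exon_count = 2L,
#'                 coding = TRUE)
#' g$exon_starts <- list(c(100L, 300L)); g$exon_ends <- list(c(200L, 400L))
#' build_components(g)
#' @export
build_components <- function(genes, chrom_sizes = NULL, config = uest_config()) {
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- g$exon_starts[[1L]]; ee <- g$exon_ends[[1L]]
    if (es[1L] < g$tx_start || ee[length(ee)] > g$tx_end)
      stop(sprintf("gene model error (%s): exon outside transcript span", g$gene_id))
    add <- function(type, s, e) {
      keep <- e > s
      if (!any(keep)) return(NULL)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 type = type, instance = seq_len(sum(keep)),
                 start = s[keep], end = e[keep], stringsAsFactors = FALSE)
    }
    parts <- list(add("exon", es, ee))
    if (length(es) > 1L)
      parts <- c(parts, list(add("intron", ee[-length(ee)], es[-1L])))
    if (g$coding) {
      # exonic pieces left of cds_start and right of cds_end
      left <- add("utr_left", pmin(es, g$cds_start), pmin(ee, g$cds_start))
      right <- add("utr_right", pmax(es, g$cds_end), pmax(ee, g$cds_end))
      if (!is.null(left)) {
        left$type <- if (g$strand == "+") "utr5" else "utr3"
        left$instance <- seq_len(nrow(left))
        parts <- c(parts, list(left))
      }
      if (!is.null(right)) {
        right$type <- if (g$strand == "+") "utr3" else "utr5"
        right$instance <- seq_len(nrow(right))
        parts <- c(parts, list(right))
      }
    }
    csize <- if (!is.null(chrom_sizes) && g$chrom %in% names(chrom_sizes))
      chrom_sizes[[g$chrom]] else Inf
    left_flank <- c(max(0L, g$tx_start - config$flank_nt), g$tx_start)
    right_flank <- c(g$tx_end, min(csize, g$tx_end + config$flank_nt))
    if (g$strand == "+") {
      parts <- c(parts, list(add("upstream", left_flank[1L], left_flank[2L]),
                             add("downstream", right_flank[1L], right_flank[2L])))
    } else {
      parts <- c(parts, list(add("upstream", right_flank[1L], right_flank[2L]),
                             add("downstream", left_flank[1L], left_flank[2L])))
    }
    rows[[i]] <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  }
  comp <- do.call(rbind, rows)
  if (is.null(comp))
    comp <- data.frame(gene_id = character(0), chrom = character(0),
                       strand = character(0), type = character(0),
                       instance = integer(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  comp$start <- as.integer(comp$start); comp$end <- as.integer(comp$end)
  rownames(comp) <- NULL
  comp
}

#' Map clusters to the genes they are in range of
#'
#' A gene is "in range" of a cluster when the cluster overlaps the gene
#' span or its `flank_nt` flanks by at least 1 nt, i.e. the cluster lies
#' within `flank_nt` of the transcript.  Clusters in range of no gene are
#' intergenic (IGR).
#'
#' @param clusters data.frame from [cluster_ests()] (needs `cluster_id,
#'   chrom, start, end`).
#' @param genes gene models from [read_genepred()].
#' @param config a [uest_config()].
#' @return A data.frame with one row per (cluster, gene) in-range pair:
#'   `cluster_id, gene_id`.
#' @export
genes_in_range <- function(clusters, genes, config = uest_config()) {
  if (nrow(clusters) == 0L || nrow(genes) == 0L)
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  spans <- data.frame(chrom = genes$chrom,
                      start = pmax(0L, genes$tx_start - config$flank_nt),
                      end = genes$tx_end + config$flank_nt)
  hits <- overlap_pairs(clusters[, c("chrom", "start", "end")], spans)
  out <- data.frame(cluster_id = clusters$cluster_id[hits$a],
                    gene_id = genes$gene_id[hits$b],
                    stringsAsFactors = FALSE)
  out[order(out$cluster_id, out$gene_id), , drop = FALSE]
}
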