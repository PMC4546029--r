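# Positional classification of unspliced EST clusters relative to gene
# models: 11 mutually exclusive classes.

#' The 11 cluster classes
#'
#' Serialized exactly as `TEX, TIN, 5PIN, 3PIN, rI, 5R, 3R, UT, DT, IGR,
#' NO_CLASS`.  The first seven are the "genic" classes.
#' @export
CLUSTER_CLASSES <- c("TEX", "TIN", "5PIN", "3PIN", "rI", "5R", "3R",
                     "UT", "DT", "IGR", "NO_CLASS")

GENIC_CLASSES <- c("TEX", "TIN", "5PIN", "3PIN", "rI", "5R", "3R")

#' Classify a cluster against a single gene
#'
#' Computes, per component *instance*, the overlap of the cluster with the
#' gene's exons, introns and flanks; an instance counts only when the
#' overlap is strictly greater than `min_component_overlap_nt` (20 nt by
#' default, a guard against small errors in annotated component borders;
#' the same threshold is applied to the flanks and to the UTR sub-labels).
#' The set of overlapped component kinds then maps to a class:
#'
#' * exon only -> `TEX` (totally exonic; UTR bases count as exon),
#' * intron only -> `TIN` (totally intronic),
#' * exactly one adjoining exon-intron pair -> `5PIN` when the exon is 5'
#'   of the intron in the gene's reading direction, else `3PIN`,
#' * one intron plus both adjacent exons -> `rI` (retained intron),
#' * exon plus upstream flank, without downstream-flank or 3'UTR
#'   overlap -> `5R`; mirror case -> `3R`,
#' * upstream flank only -> `UT`; downstream flank only -> `DT`,
#' * anything else -> `NO_CLASS`.
#'
#' @param cluster one cluster (any object with `start` and `end`; `chrom`
#'   is assumed to match the gene's).
#' @param components component table from [build_components()] restricted
#'   to one gene (or a table from which the rows of `gene_id` are taken).
#' @param gene_id id of the gene to classify against.
#' @param config a [uest_config()].
#' @return A single class label.
#' @export
classify_vs_gene <- function(cluster, components, gene_id, config = uest_config()) {
  comp <- components[components$gene_id == gene_id, , drop = FALSE]
  if (nrow(comp) == 0L)
    stop("classify_vs_gene: no components for gene ", gene_id)
  classify_one(cluster$start, cluster$end, comp, comp$strand[1L],
               config$min_component_overlap_nt)
}

# core rule table on one (start, end) against one gene's component rows
classify_one <- function(cstart, cend, comp, strand, thr) {
  ov <- overlap_width(cstart, cend, comp$start, comp$end)
  hit <- ov > thr
  exon_idx <- comp$instance[comp$type == "exon" & hit]
  intron_idx <- comp$instance[comp$type == "intron" & hit]
  up <- any(comp$type == "upstream" & hit)
  down <- any(comp$type == "downstream" & hit)
  utr5 <- any(comp$type == "utr5" & hit)
  utr3 <- any(comp$type == "utr3" & hit)
  n_exon <- length(exon_idx); n_intron <- length(intron_idx)

  if (!n_exon && !n_intron && !up && !down) return("NO_CLASS")
  if (n_exon && !n_intron && !up && !down) return("TEX")
  if (!n_exon && n_intron && !up && !down) return("TIN")
  if (n_exon && n_intron == 1L && !up && !down) {
    i <- intron_idx  # intron i lies between exons i and i+1 (genomic order)
    if (n_exon == 1L && exon_idx %in% c(i, i + 1L)) {
      # genomic-left exon is 5' on "+" genes, 3' on "-" genes
      exon_is_left <- exon_idx == i
      exon_is_5prime <- xor(exon_is_left, strand == "-")
      return(if (exon_is_5prime) "5PIN" else "3PIN")
    }
    if (n_exon == 2L && setequal(exon_idx, c(i, i + 1L))) return("rI")
  }
  if (n_exon && up && !down && !utr3) return("5R")
  if (n_exon && down && !up && !utr5) return("3R")
  if (up && !down && !n_exon && !n_intron) return("UT")
  if (down && !up && !n_exon && !n_intron) return("DT")
  "NO_CLASS"
}

# reduce the per-gene class set of one cluster to its final label
resolve_classes <- function(labels) {
  if (length(labels) == 0L) return("IGR")
  u <- unique(labels)
  if (length(u) == 1L) return(u)
  genic <- u[u %in% GENIC_CLASSES]
  rest <- u[!u %in% GENIC_CLASSES]
  # conflicts with UT/DT only are resolved in favour of the genic class:
  # the extra upstream/downstream-flank overlap of a neighbouring gene is
  # ignored, otherwise dense regions would be unclassifiable
  if (length(genic) == 1L && all(rest %in% c("UT", "DT"))) return(genic)
  "NO_CLASS"
}

#' Classify all clusters
#'
#' Applies [classify_vs_gene()] to every (cluster, in-range gene) pair and
#' resolves multi-gene conflicts: a cluster in range of no gene is `IGR`
#' (intergenic, more than `flank_nt` from every transcript end); a cluster
#' whose per-gene classes all agree keeps that class; a conflict between
#' exactly one genic class (`TEX, TIN, 5PIN, 3PIN, rI, 5R, 3R`) and
#' upstream/downstream-only classes (`UT`/`DT`) keeps the genic class; any
#' other conflict is `NO_CLASS`.  Every cluster receives exactly one label.
#'
#' @param clusters data.frame from [cluster_ests()].
#' @param genes gene models from [read_genepred()].
#' @param components optional precomputed [build_components()] table.
#' @param config a [uest_config()].
#' @param in_range optional precomputed [genes_in_range()] mapping.
#' @return `clusters` with columns `class` and `genes` (comma-separated
#'   in-range gene ids) appended.
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 1, n_genes = 2))
#' res <- run_all(scn$files, file.path(tempdir(), "toy-run"),
#'                excluded_chroms = scn$excluded_chroms)
#' class_summary(res$classes$class)
#' @export
classify_clusters <- function(clusters, genes, components = NULL,
                              config = uest_config(), in_range = NULL) {
  if (is.null(components)) components <- build_components(genes, config = config)
  if (is.null(in_range)) in_range <- genes_in_range(clusters, genes, config)
  comp_by_gene <- split(components, components$gene_id)
  genes_by_cluster <- split(in_range$gene_id, in_range$cluster_id)
  cls <- character(nrow(clusters))
  gene_col <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    gids <- genes_by_cluster[[clusters$cluster_id[i]]]
    if (is.null(gids)) gids <- character(0)
    labels <- vapply(gids, function(g) {
      comp <- comp_by_gene[[g]]
      classify_one(clusters$start[i], clusters$end[i], comp, comp$strand[1L],
                   config$min_component_overlap_nt)
    }, character(1))
    cls[i] <- resolve_classes(labels)
    gene_col[i] <- paste(gids, collapse = ",")
  }
  clusters$class <- cls
  clusters$genes <- gene_col
  clusters
}

#' Per-class cluster counts
#'
#' @param classes character vector of class labels (e.g. the `class`
#'   column of [classify_clusters()] output).
#' @return A named integer vector over all 11 classes (zeros included);
#'   the counts partition the cluster set.  `NO_CLASS` collects the
#'   ambiguous clusters, which are excluded from class-specific analyses.
#' @export
class_summary <- function(classes) {
  bad <- setdiff(unique(classes), CLUSTER_CLASSES)
  if (length(bad)) stop("unknown class label: ", bad[1L])
  tab <- table(factor(classes, levels = CLUSTER_CLASSES))
  setNames(as.integer(tab), CLUSTER_CLASSES)
}
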