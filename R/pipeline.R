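# End-to-end pipeline over a file bundle, with a completion MANIFEST.

PIPELINE_STAGES <- c("filter", "cluster", "classify", "evidence", "uarna",
                     "orthology", "conservation")

#' Run the whole analysis on a file bundle
#'
#' Executes the stages in fixed order -- filter, cluster, classify,
#' evidence, uaRNA, orthology, conservation -- writing one flat file per
#' stage plus a `MANIFEST` recording each stage as `completed` or
#' `skipped`.  Stages whose optional inputs are absent are skipped;
#' missing required inputs (`psl_a`, `genes_a`) fail before any stage
#' runs.  Outputs contain no timestamps, so identical inputs give
#' byte-identical outputs.
#'
#' @param inputs named list of paths (as in a [generate_scenario()]
#'   `files` element): required `psl_a`, `genes_a`; optional `numts_a`,
#'   `cage_a`, `chromatin_a`, `rnaseq_a` (vector), `conservation_a`, and
#'   for two-genome runs `psl_b`, `genes_b`, `cage_b`, `chains_ab`,
#'   `chains_ba`.
#' @param out_dir output directory, created if needed.
#' @param config a [uest_config()].
#' @param excluded_chroms chromosomes dropped by the haplotype filter.
#' @return Invisibly, a list with the in-memory stage results: `funnel`,
#'   `clusters`, `classes`, `evidence`, `uarna`, `orthologs`,
#'   `ortholog_summary`, `conservation`, `manifest`.
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 1, n_genes = 2))
#' res <- run_all(scn$files, file.path(tempdir(), "uest_demo"),
#'                excluded_chroms = scn$excluded_chroms)
#' res$manifest
#' @export
run_all <- function(inputs, out_dir, config = uest_config(),
                    excluded_chroms = character()) {
  required <- c("psl_a", "genes_a")
  missing_in <- setdiff(required, names(inputs))
  present <- vapply(inputs[intersect(required, names(inputs))],
                    function(p) all(file.exists(p)), logical(1))
  if (length(missing_in) || !all(present))
    stop("run_all: required input missing: ",
         paste(c(missing_in, names(present)[!present]), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- setNames(rep("skipped", length(PIPELINE_STAGES)), PIPELINE_STAGES)
  res <- list()
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  have <- function(key) !is.null(inputs[[key]]) && all(file.exists(inputs[[key]]))

  # filter + cluster
  psl <- read_psl(inputs$psl_a)
  numts <- if (have("numts_a")) read_bed(inputs$numts_a) else NULL
  flt <- filter_unspliced(psl, numts, excluded_chroms, config)
  status["filter"] <- "completed"
  clusters <- cluster_ests(flt$alignments, config, flt$report)
  res$funnel <- attr(clusters, "report")
  tsv(data.frame(stage = names(res$funnel), n = unname(unclass(res$funnel))),
      "funnel.tsv")
  write_clusters_bed(clusters, file.path(out_dir, "clusters.bed"))
  status["cluster"] <- "completed"
  res$clusters <- clusters

  # classify
  genes <- read_genepred(inputs$genes_a)
  components <- build_components(genes, config = config)
  classes <- classify_clusters(clusters, genes, components, config)
  tsv(classes[, c("cluster_id", "chrom", "start", "end", "n_members",
                  "class", "genes")], "classes.tsv")
  status["classify"] <- "completed"
  res$classes <- classes

  # evidence
  peaks <- if (have("cage_a")) read_bed(inputs$cage_a, 6L) else NULL
  segments <- if (have("chromatin_a")) read_bed(inputs$chromatin_a, 4L) else NULL
  tracks <- if (have("rnaseq_a")) lapply(inputs$rnaseq_a, read_bedgraph) else NULL
  if (!is.null(peaks) || !is.null(segments) || !is.null(tracks)) {
    res$evidence <- evidence_matrix(classes, genes, components, peaks,
                                    segments, tracks, config)
    tsv(res$evidence, "evidence.tsv")
    status["evidence"] <- "completed"
  }

  # uaRNA
  if (!is.null(peaks)) {
    res$uarna <- call_uarnas(classes, genes, "cage", peaks = peaks,
                             components = components, config = config)
    tsv(res$uarna, "uarna_cage.tsv")
    status["uarna"] <- "completed"
  }
  if (!is.null(segments)) {
    res$uarna_chromatin <- call_uarnas(classes, genes, "chromatin",
                                       segments = segments,
                                       components = components,
                                       config = config)
    tsv(res$uarna_chromatin, "uarna_chromatin.tsv")
    status["uarna"] <- "completed"
  }

  # orthology
  if (have("psl_b") && have("genes_b") && have("chains_ab") &&
        have("chains_ba")) {
    psl_b <- read_psl(inputs$psl_b)
    flt_b <- filter_unspliced(psl_b, NULL, excluded_chroms, config)
    clusters_b <- cluster_ests(flt_b$alignments, config)
    genes_b <- read_genepred(inputs$genes_b)
    classes_b <- classify_clusters(clusters_b, genes_b, config = config)
    pairs <- pair_orthologs(classes, classes_b,
                            read_chain(inputs$chains_ab),
                            read_chain(inputs$chains_ba),
                            config$min_mapped_frac)
    tsv(pairs, "orthologs.tsv")
    res$orthologs <- pairs
    res$clusters_b <- classes_b
    res$ortholog_summary <- conservation_summary(pairs, classes, classes_b)
    tsv(data.frame(stat = names(res$ortholog_summary),
                   n = unname(res$ortholog_summary)), "ortholog_summary.tsv")
    status["orthology"] <- "completed"
  }

  # conservation
  if (have("conservation_a")) {
    track <- read_wiggle(inputs$conservation_a)
    exons <- data.frame(chrom = rep(genes$chrom, genes$exon_count),
                        start = unlist(genes$exon_starts),
                        end = unlist(genes$exon_ends))
    introns <- components[components$type == "intron",
                          c("chrom", "start", "end"), drop = FALSE]
    res$conservation <- class_conservation(
      classes, track, backgrounds = list(exons = exons, introns = introns))
    tsv(res$conservation, "conservation.tsv")
    status["conservation"] <- "completed"
  }

  writeLines(paste(names(status), status, sep = "\t"),
             file.path(out_dir, "MANIFEST"))
  res$manifest <- status
  invisible(res)
}

#' Parse a flat key = value configuration file
#'
#' Lines of the form `key = value` (`#` comments allowed); numeric values
#' are coerced.  Keys matching [uest_config()] arguments override the
#' defaults.
#'
#' @param path path to the configuration file.
#' @return A [uest_config()].
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("config parse error: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(args) <- keys
  known <- intersect(names(args), names(formals(uest_config)))
  do.call(uest_config, args[known])
}
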