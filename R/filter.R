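# Successive alignment filters: haplotype chromosomes, intron-sized gaps,
# mismatch rate, NUMT contamination.

FUNNEL_STAGES <- c("input", "after_haplotype", "after_gap", "after_mismatch",
                   "after_numt", "unspliced_ests", "clusters")

#' Filter EST alignments down to clean unspliced ESTs
#'
#' Applies, in order: (1) removal of alignments on excluded chromosomes
#' (alternative haplotypes, to avoid counting identical ESTs twice);
#' (2) removal of alignments whose largest single target-side gap exceeds
#' `max_gap_nt` -- this discards spliced ESTs and intron-like unannotated
#' gaps; (3) removal of alignments with a mismatch fraction above
#' `max_mismatch_frac`; (4) removal of alignments overlapping a NUMT
#' (nuclear copy of mitochondrial DNA) region by at least 1 nt, since
#' ESTs of unspliced mitochondrial transcripts mapping to recent NUMTs
#' cannot be told apart from genuine transcription.
#'
#' @param psl alignments as returned by [read_psl()].
#' @param numts optional data.frame of NUMT intervals (`chrom, start, end`).
#' @param excluded_chroms character vector of chromosome names to drop.
#' @param config a [uest_config()].
#' @return A list with `alignments` (the surviving rows) and `report`, a
#'   `uest_funnel` object recording the count surviving each successive
#'   filter (the `clusters` entry stays `NA` until [cluster_ests()] runs).
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 1, n_genes = 2))
#' psl <- read_psl(scn$files$psl_a)
#' flt <- filter_unspliced(psl, read_bed(scn$files$numts_a),
#'                         scn$excluded_chroms)
#' flt$report
#' @export
filter_unspliced <- function(psl, numts = NULL, excluded_chroms = character(),
                             config = uest_config()) {
  counts <- c(input = nrow(psl))
  psl <- psl[!(psl$tName %in% excluded_chroms), , drop = FALSE]
  counts["after_haplotype"] <- nrow(psl)
  gap <- if (config$gap_mode == "largest") psl_largest_gap(psl) else psl$tBaseInsert
  psl <- psl[gap <= config$max_gap_nt, , drop = FALSE]
  counts["after_gap"] <- nrow(psl)
  psl <- psl[psl_mismatch_frac(psl) <= config$max_mismatch_frac, , drop = FALSE]
  counts["after_mismatch"] <- nrow(psl)
  if (!is.null(numts) && nrow(numts) > 0L && nrow(psl) > 0L) {
    hit <- overlaps_any(psl_intervals(psl), numts)
    psl <- psl[!hit, , drop = FALSE]
  }
  counts["after_numt"] <- nrow(psl)
  counts["unspliced_ests"] <- nrow(psl)
  counts["clusters"] <- NA_integer_
  rownames(psl) <- NULL
  list(alignments = psl,
       report = structure(counts[FUNNEL_STAGES], class = "uest_funnel"))
}

#' @export
print.uest_funnel <- function(x, ...) {
  cat("uEST filter funnel (surviving counts)\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm,
                                   ifelse(is.na(x[[nm]]), "-", x[[nm]])))
  invisible(x)
}

#' @export
format.uest_funnel <- function(x, ...) {
  paste(names(x), unclass(x), sep = "=", collapse = " ")
}
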