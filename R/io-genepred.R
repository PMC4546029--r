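# UCSC genePred gene-structure format (RefSeq Genes track).

#' Read a genePred gene model file
#'
#' Parses the 10-column UCSC genePred format (`name chrom strand txStart
#' txEnd cdsStart cdsEnd exonCount exonStarts exonEnds`; extra trailing
#' columns are ignored).  Exon lists are comma-terminated.  A record with
#' `cdsStart == cdsEnd` is a non-coding transcript.  All coordinates are
#' 0-based half-open, as in the format.
#'
#' @param path path to a genePred file.
#' @return A data.frame with columns `gene_id, chrom, strand, tx_start,
#'   tx_end, cds_start, cds_end, exon_count, coding` and list columns
#'   `exon_starts`, `exon_ends` (integer vectors, genomic order).
#' @seealso [write_genepred()], [build_components()]
#' @export
read_genepred <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_genepred())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L))
    stop(sprintf("genePred parse error at line %d: expected >= 10 columns, found %d",
                 which(nf < 10L)[1L], nf[nf < 10L][1L]))
  take <- function(k) vapply(fields, `[[`, character(1), k)
  gp <- data.frame(gene_id = take(1L), chrom = take(2L), strand = take(3L),
                   stringsAsFactors = FALSE)
  ints <- lapply(4:8, function(k) suppressWarnings(as.integer(take(k))))
  names(ints) <- c("tx_start", "tx_end", "cds_start", "cds_end", "exon_count")
  for (nm in names(ints)) {
    if (anyNA(ints[[nm]]))
      stop(sprintf("genePred parse error at line %d: non-numeric %s",
                   which(is.na(ints[[nm]]))[1L], nm))
    gp[[nm]] <- ints[[nm]]
  }
  gp$exon_starts <- parse_int_list(take(9L))
  gp$exon_ends <- parse_int_list(take(10L))
  for (i in seq_len(nrow(gp))) {
    es <- gp$exon_starts[[i]]; ee <- gp$exon_ends[[i]]
    if (length(es) != gp$exon_count[i] || length(ee) != gp$exon_count[i])
      stop(sprintf("genePred parse error at line %d: exonCount %d does not match exon lists",
                   i, gp$exon_count[i]))
    if (any(ee <= es))
      stop(sprintf("genePred parse error at line %d: empty or inverted exon", i))
    if (length(es) > 1L && any(es[-1L] < ee[-length(ee)]))
      stop(sprintf("genePred parse error at line %d: exons overlap or are unsorted", i))
    if (es[1L] < gp$tx_start[i] || ee[length(ee)] > gp$tx_end[i])
      stop(sprintf("gene model error at line %d: exon outside transcript span", i))
    if (!gp$strand[i] %in% c("+", "-"))
      stop(sprintf("genePred parse error at line %d: strand must be + or -", i))
  }
  gp$coding <- gp$cds_start < gp$cds_end
  gp
}

empty_genepred <- function() {
  data.frame(gene_id = character(0), chrom = character(0), strand = character(0),
             tx_start = integer(0), tx_end = integer(0),
             cds_start = integer(0), cds_end = integer(0),
             exon_count = integer(0),
             exon_starts = I(list()), exon_ends = I(list()),
             coding = logical(0), stringsAsFactors = FALSE)
}

#' Write gene models to genePred
#'
#' @param genes data.frame as returned by [read_genepred()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(genes, path) {
  comma <- function(l) vapply(l, function(v) paste0(paste(v, collapse = ","), ","),
                              character(1))
  lines <- paste(genes$gene_id, genes$chrom, genes$strand,
                 genes$tx_start, genes$tx_end, genes$cds_start, genes$cds_end,
                 genes$exon_count, comma(genes$exon_starts), comma(genes$exon_ends),
                 sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
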