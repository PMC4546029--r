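# Small programmatic fixtures shared across the test files.

# one gene model row in the read_genepred() layout
make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      exon_starts, exon_ends,
                      cds_start = exon_starts[1L],
                      cds_end = exon_ends[length(exon_ends)]) {
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  tx_start = exon_starts[1L], tx_end = exon_ends[length(exon_ends)],
                  cds_start = cds_start, cds_end = cds_end,
                  exon_count = length(exon_starts),
                  coding = cds_start < cds_end, stringsAsFactors = FALSE)
  g$exon_starts <- list(as.integer(exon_starts))
  g$exon_ends <- list(as.integer(exon_ends))
  g
}

# a random valid gene model for property tests
random_gene <- function(id = "g1", chrom = "chr1") {
  n_ex <- sample(1:5, 1L)
  elen <- sample(60:300, n_ex, replace = TRUE)
  ilen <- if (n_ex > 1L) sample(60:400, n_ex - 1L, replace = TRUE) else integer(0)
  gs <- sample(2000:4000, 1L)
  es <- integer(n_ex); ee <- integer(n_ex)
  pos <- gs
  for (k in seq_len(n_ex)) {
    es[k] <- pos; ee[k] <- pos + elen[k]
    pos <- ee[k] + if (k < n_ex) ilen[k] else 0L
  }
  strand <- sample(c("+", "-"), 1L)
  if (runif(1) < 0.8) {
    cds <- sort(sample(gs:ee[n_ex], 2L))
    cds_start <- cds[1L]; cds_end <- cds[2L]
  } else {
    cds_start <- cds_end <- gs
  }
  make_gene(id, chrom, strand, es, ee, cds_start, cds_end)
}

# a random cluster interval near the gene, sometimes snapped to a
# component boundary at exactly the 20/21-nt overlap edge
random_cluster_near <- function(gene, flank) {
  lo <- max(0L, gene$tx_start - flank)
  hi <- gene$tx_end + flank
  if (runif(1) < 0.4) {
    edges <- unique(c(gene$exon_starts[[1L]], gene$exon_ends[[1L]],
                      gene$tx_start, gene$tx_end))
    edge <- sample(edges, 1L)
    delta <- sample(c(19L, 20L, 21L, 22L), 1L)
    if (runif(1) < 0.5) {
      s <- edge - delta; e <- s + sample(30:300, 1L)
    } else {
      e <- edge + delta; s <- e - sample(30:300, 1L)
    }
  } else {
    s <- sample(lo:(hi - 31L), 1L)
    e <- s + sample(30:400, 1L)
  }
  c(max(lo, s), min(hi, e))
}

# one identity-like chain with explicit blocks
make_chain <- function(blocks, t_name = "chrA", q_name = "chrB",
                       t_size = 100000L, q_size = 100000L,
                       t_start = 0L, q_start = 0L, q_strand = "+",
                       chain_id = "1") {
  b <- do.call(rbind, blocks)
  colnames(b) <- c("size", "dt", "dq")
  list(score = sum(b[, "size"]), t_name = t_name, t_size = t_size,
       t_strand = "+", t_start = t_start,
       t_end = t_start + sum(b[, "size"]) + sum(b[, "dt"]),
       q_name = q_name, q_size = q_size, q_strand = q_strand,
       q_start = q_start,
       q_end = q_start + sum(b[, "size"]) + sum(b[, "dq"]),
       chain_id = chain_id, blocks = b)
}

# a random chain with indels, sized to stay inside the declared sequences
random_chain <- function(t_name = "chrA", q_name = "chrB", q_strand = "+",
                         chain_id = "1") {
  n_blocks <- sample(1:6, 1L)
  blocks <- lapply(seq_len(n_blocks), function(k) {
    size <- sample(50:400, 1L)
    if (k == n_blocks) c(size, 0L, 0L) else
      c(size, sample(0:120, 1L), sample(0:120, 1L))
  })
  t_start <- sample(0:500, 1L)
  q_start <- sample(0:500, 1L)
  make_chain(blocks, t_name, q_name, t_size = 10000L, q_size = 10000L,
             t_start = t_start, q_start = q_start, q_strand = q_strand,
             chain_id = chain_id)
}

# single-block PSL row helper mirroring the generator's layout
simple_psl_row <- function(qname, tname, start, len, tsize = 100000L,
                           mism = 0L, gap_after = NULL, second_len = 60L) {
  blocks <- if (is.null(gap_after)) cbind(start = start, size = len) else
    cbind(start = c(start, start + len + gap_after),
          size = c(len, second_len))
  uestr:::psl_row(qname, tname, tsize, blocks, mism = mism)
}

expect_same_clusters <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$n_members, want$n_members)
  sort_members <- function(x) vapply(strsplit(x, ",", fixed = TRUE),
                                     function(v) paste(sort(v), collapse = ","),
                                     character(1))
  expect_equal(sort_members(got$members), sort_members(want$members))
}
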