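# Gene-model decomposition and the in-range mapping.

test_that("components of a two-exon gene are constructed on both strands", {
  cfg <- uest_config()
  g <- make_gene("g1", "chr1", "+", c(100L, 300L), c(200L, 400L), 150L, 350L)
  comp <- build_components(g, config = cfg)
  get <- function(tp) comp[comp$type == tp, c("start", "end")]
  expect_equal(get("utr5"), data.frame(start = 100L, end = 150L),
               ignore_attr = TRUE)
  expect_equal(get("utr3"), data.frame(start = 350L, end = 400L),
               ignore_attr = TRUE)
  expect_equal(get("intron"), data.frame(start = 200L, end = 300L),
               ignore_attr = TRUE)
  expect_equal(get("upstream"), data.frame(start = 0L, end = 100L),
               ignore_attr = TRUE)  # truncated at the chromosome start
  expect_equal(get("downstream"), data.frame(start = 400L, end = 5400L),
               ignore_attr = TRUE)
  # strand mirror: upstream flank moves right of txEnd, UTRs swap
  gm <- make_gene("g1", "chr1", "-", c(100L, 300L), c(200L, 400L), 150L, 350L)
  compm <- build_components(gm, config = cfg)
  getm <- function(tp) compm[compm$type == tp, c("start", "end")]
  expect_equal(getm("utr5"), data.frame(start = 350L, end = 400L),
               ignore_attr = TRUE)
  expect_equal(getm("upstream"), data.frame(start = 400L, end = 5400L),
               ignore_attr = TRUE)
  expect_equal(getm("downstream"), data.frame(start = 0L, end = 100L),
               ignore_attr = TRUE)
  # flanks clipped by chrom_sizes
  compc <- build_components(g, chrom_sizes = c(chr1 = 5000L), config = cfg)
  expect_equal(max(compc$end), 5000L)
})

test_that("intron plus exon bases conserve the transcript span", {
  set.seed(51)
  for (rep in 1:20) {
    g <- random_gene()
    comp <- build_components(g, config = uest_config(flank_nt = 500L))
    ei <- comp[comp$type %in% c("exon", "intron"), ]
    expect_equal(sum(ei$end - ei$start), g$tx_end - g$tx_start)
    # single-exon genes have no introns
    if (g$exon_count == 1L) expect_false("intron" %in% comp$type)
    # UTR pieces partition the non-CDS exonic bases of coding genes
    if (g$coding) {
      exonic <- sum(comp$end[comp$type == "exon"] - comp$start[comp$type == "exon"])
      utr <- comp[comp$type %in% c("utr5", "utr3"), ]
      cds_exonic <- sum(pmax(0L, pmin(comp$end[comp$type == "exon"], g$cds_end) -
                               pmax(comp$start[comp$type == "exon"], g$cds_start)))
      expect_equal(sum(utr$end - utr$start) + cds_exonic, exonic)
    }
  }
})

test_that("per-base component labels equal the independent painter", {
  set.seed(61)
  for (rep in 1:50) {
    g <- random_gene()
    comp <- build_components(g, config = uest_config(flank_nt = 400L))
    p <- oracle_paint_gene(g, 400L)
    for (tp in c("exon", "intron", "upstream", "downstream")) {
      rows <- comp[comp$type == tp, , drop = FALSE]
      covered <- unlist(Map(function(s, e) s:(e - 1L), rows$start, rows$end))
      if (is.null(covered)) covered <- integer(0)
      expect_setequal(covered, p$pos[!is.na(p$kind) & p$kind == tp])
    }
  }
})

test_that("genes_in_range uses the 5-kb flanks and matches the all-pairs oracle", {
  cfg <- uest_config()
  genes <- rbind(make_gene("near", "chr1", "+", 5049L, 9000L),
                 make_gene("boundary", "chr1", "+", 5050L, 9000L),
                 make_gene("farther", "chr1", "+", 10051L, 20000L))
  clusters <- data.frame(cluster_id = "c1", chrom = "chr1", start = 0L,
                         end = 50L)
  m <- genes_in_range(clusters, genes, cfg)
  # the flank of "near" starts at 49 and touches the cluster by 1 nt; the
  # flank of "boundary" starts exactly at the (half-open) cluster end and
  # the flank of "farther" at 5051, so neither is in range
  expect_equal(m$gene_id, "near")
  set.seed(71)
  genes <- do.call(rbind, lapply(1:15, function(i)
    random_gene(sprintf("g%02d", i),
                sample(c("chr1", "chr2"), 1L))))
  genes$tx_start <- genes$tx_start + sample(0:30000, 15L)
  shift <- genes$tx_start - vapply(genes$exon_starts, `[[`, integer(1), 1L)
  for (i in 1:15) {
    genes$exon_starts[[i]] <- genes$exon_starts[[i]] + shift[i]
    genes$exon_ends[[i]] <- genes$exon_ends[[i]] + shift[i]
    genes$tx_end[i] <- genes$exon_ends[[i]][genes$exon_count[i]]
    genes$cds_start[i] <- genes$cds_start[i] + shift[i]
    genes$cds_end[i] <- genes$cds_end[i] + shift[i]
  }
  clusters <- data.frame(cluster_id = sprintf("c%02d", 1:40),
                         chrom = sample(c("chr1", "chr2"), 40L, replace = TRUE),
                         start = sample(0:40000, 40L))
  clusters$end <- clusters$start + sample(50:500, 40L, replace = TRUE)
  expect_equal(genes_in_range(clusters, genes, cfg),
               oracle_in_range(clusters, genes),
               ignore_attr = TRUE)
})
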