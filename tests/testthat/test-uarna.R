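# uaRNA candidate calling.

uarna_fixture <- function() {
  # + strand gene, 3'UTR [3500, 4000), 5'UTR [1000, 1500)
  genes <- make_gene("g1", "chr1", "+", c(1000L, 3000L), c(2000L, 4000L),
                     1500L, 3500L)
  clusters <- data.frame(
    cluster_id = c("hit", "both_utrs", "no_tss", "igr"),
    chrom = "chr1",
    start = c(3600L, 1400L, 3650L, 50000L),
    end = c(4200L, 4200L, 4150L, 50400L))
  list(genes = genes, clusters = classify_clusters(clusters, genes))
}

test_that("uaRNA calls require 3'UTR overlap, clean 5'UTR and TSS evidence", {
  fx <- uarna_fixture()
  peaks <- data.frame(chrom = "chr1", start = c(3610L, 1410L),
                      end = c(3620L, 1420L), name = "p", score = 1L,
                      strand = "+", stringsAsFactors = FALSE)
  got <- call_uarnas(fx$clusters, fx$genes, "cage", peaks = peaks)
  # only "hit": overlaps utr3 by 400, no utr5, forward peak in its window;
  # "both_utrs" also touches the 5'UTR, "no_tss" has no peak, "igr" is far
  expect_equal(got$cluster_id, "hit")
  expect_equal(got$host_genes, "g1")
  expect_equal(got$orientation, "forward")
  # chromatin evidence instead of CAGE
  segs <- data.frame(chrom = "chr1", start = c(3610L, 3610L),
                     end = c(3660L, 3660L), name = c("TSS", "T"),
                     stringsAsFactors = FALSE)
  got2 <- call_uarnas(fx$clusters, fx$genes, "chromatin", segments = segs)
  expect_setequal(got2$cluster_id, c("hit", "no_tss"))
  # a T-only segment is not TSS evidence
  got3 <- call_uarnas(fx$clusters, fx$genes, "chromatin",
                      segments = segs[segs$name == "T", ])
  expect_equal(nrow(got3), 0L)
  expect_error(call_uarnas(fx$clusters, fx$genes, "cage"), "requires peaks")
})

test_that("bidirectional clusters and sub-threshold 3'UTR overlaps are rejected", {
  fx <- uarna_fixture()
  both <- data.frame(chrom = "chr1", start = c(3610L, 4185L),
                     end = c(3620L, 4195L), name = "p", score = 1L,
                     strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_equal(nrow(call_uarnas(fx$clusters[1L, ], fx$genes, "cage",
                                peaks = both)), 0L)
  # exactly 20 nt of 3'UTR overlap is not > 20
  cl <- classify_clusters(data.frame(cluster_id = "edge", chrom = "chr1",
                                     start = 3980L, end = 4300L), fx$genes)
  pk <- data.frame(chrom = "chr1", start = 3985L, end = 3995L, name = "p",
                   score = 1L, strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(call_uarnas(cl, fx$genes, "cage", peaks = pk)), 0L)
  cl21 <- classify_clusters(data.frame(cluster_id = "edge", chrom = "chr1",
                                       start = 3979L, end = 4300L), fx$genes)
  expect_equal(nrow(call_uarnas(cl21, fx$genes, "cage", peaks = pk)), 1L)
})

test_that("planted uaRNAs are recovered exactly among decoys", {
  scn <- generate_scenario(scenario_config(seed = 13, n_genes = 8, n_igr = 4,
                                           n_uarna = 5))
  psl <- read_psl(scn$files$psl_a)
  clusters <- cluster_ests(filter_unspliced(psl)$alignments)
  genes <- read_genepred(scn$files$genes_a)
  classes <- classify_clusters(clusters, genes)
  peaks <- read_bed(scn$files$cage_a, 6L)
  calls <- call_uarnas(classes, genes, "cage", peaks = peaks)
  truth <- scn$truth$clusters
  want <- truth[truth$is_uarna, ]
  got <- classes[classes$cluster_id %in% calls$cluster_id, ]
  expect_equal(nrow(got), nrow(want))  # precision = recall = 1
  expect_setequal(paste(got$chrom, got$start, got$end),
                  paste(want$chrom, want$start, want$end))
  # postcondition: no candidate overlaps any in-range gene 5'UTR above
  # threshold, and IGR clusters are never candidates
  expect_false(any(got$class == "IGR"))
  comp <- build_components(genes)
  utr5 <- comp[comp$type == "utr5", ]
  for (i in seq_len(nrow(got))) {
    w <- uestr:::overlap_width(got$start[i], got$end[i], utr5$start, utr5$end)
    expect_true(all(w <= 20L))
  }
})

test_that("intersect_calls is plain set algebra", {
  a <- data.frame(cluster_id = c("x", "y", "z"))
  b <- data.frame(cluster_id = c("y", "w"))
  got <- intersect_calls(a, b)
  expect_equal(got$both, "y")
  expect_equal(got$cage_only, c("x", "z"))
  expect_equal(got$chromatin_only, "w")
  same <- intersect_calls(a, a)
  expect_equal(same$both, sort(a$cluster_id))
  expect_length(same$cage_only, 0L)
  disjoint <- intersect_calls(a, data.frame(cluster_id = "q"))
  expect_length(disjoint$both, 0L)
  set.seed(111)
  for (rep in 1:5) {
    u <- sample(letters, 10L)
    v <- sample(letters, 8L)
    got <- intersect_calls(data.frame(cluster_id = u),
                           data.frame(cluster_id = v))
    expect_setequal(got$both, intersect(u, v))
    expect_lte(length(got$both), min(length(u), length(v)))
  }
})
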