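# CAGE orientation, expression breadth, chromatin and RNA-seq support.

peak <- function(s, e, strand, chrom = "chr1")
  data.frame(chrom = chrom, start = s, end = e, name = "p", score = 1L,
             strand = strand, stringsAsFactors = FALSE)

test_that("orient_by_cage uses the 84-nt end windows", {
  cl <- data.frame(chrom = "chr1", start = 1000L, end = 3000L)
  expect_equal(orient_by_cage(cl, peak(1010L, 1020L, "+")), "forward")
  expect_equal(orient_by_cage(cl, peak(2990L, 2995L, "-")), "reverse")
  # both ends at once: bidirectional, disregarded downstream
  expect_equal(orient_by_cage(cl, rbind(peak(1010L, 1020L, "+"),
                                        peak(2990L, 2995L, "-"))),
               "bidirectional")
  # the forward window is [1000, 1084): a + peak at 1084 misses it
  expect_equal(orient_by_cage(cl, peak(1084L, 1090L, "+")), "none")
  expect_equal(orient_by_cage(cl, peak(1083L, 1090L, "+")), "forward")
  # a - peak near the start does not orient, nor a + peak near the end
  expect_equal(orient_by_cage(cl, peak(1010L, 1020L, "-")), "none")
  expect_equal(orient_by_cage(cl, peak(2990L, 2995L, "+")), "none")
  # clusters shorter than the window are clipped, not skipped
  short <- data.frame(chrom = "chr1", start = 0L, end = 50L)
  expect_equal(orient_by_cage(short, peak(40L, 45L, "+")), "forward")
})

test_that("orientation matches the all-pairs oracle and is evidence-monotone", {
  set.seed(101)
  for (rep in 1:10) {
    clusters <- data.frame(chrom = "chr1",
                           start = seq(0L, by = 3000L, length.out = 20L))
    clusters$end <- clusters$start + sample(60:2500, 20L, replace = TRUE)
    n <- 60L
    peaks <- data.frame(chrom = "chr1", start = sample(0:60000, n),
                        name = "p", score = 1L,
                        strand = sample(c("+", "-"), n, replace = TRUE))
    peaks$end <- peaks$start + sample(5:30, n, replace = TRUE)
    got <- orient_by_cage(clusters, peaks)
    want <- vapply(seq_len(nrow(clusters)), function(i)
      oracle_orient(clusters[i, ], peaks), character(1))
    expect_equal(got, want)
    # adding peaks never silences an oriented cluster
    more <- rbind(peaks, peak(100L, 110L, "+"))
    got2 <- orient_by_cage(clusters, more)
    moved_off <- got %in% c("forward", "reverse") & got2 == "none"
    expect_false(any(moved_off))
  }
})

test_that("cell breadth counts orienting cell types, order-invariantly", {
  cl <- data.frame(chrom = "chr1", start = c(0L, 5000L), end = c(1000L, 6000L))
  sets <- list(c1 = peak(10L, 20L, "+"), c2 = peak(30L, 40L, "+"),
               c3 = peak(5990L, 5995L, "-"))
  br <- cell_breadth(cl, sets)
  expect_equal(br$breadth, c(2L, 1L))
  expect_equal(cell_breadth(cl, rev(sets))$breadth, br$breadth)
  # a bidirectional cell does not count
  sets$c3 <- rbind(peak(10L, 20L, "+"), peak(990L, 995L, "-"))
  expect_equal(cell_breadth(cl, sets)$breadth[1L], 2L)
  expect_equal(sum(br$histogram), sum(br$breadth >= 1L))
})

test_that("chromatin flags are unions over cell lines", {
  cl <- data.frame(cluster_id = c("c1", "c2"), chrom = "chr1",
                   start = c(0L, 5000L), end = c(1000L, 6000L))
  segs <- data.frame(chrom = "chr1", start = c(500L, 900L, 7000L),
                     end = c(600L, 1200L, 7500L),
                     name = c("T", "R", "TSS"), stringsAsFactors = FALSE)
  got <- chromatin_support(cl, segs)
  expect_equal(got$has_T_state, c(TRUE, FALSE))
  expect_equal(got$has_TSS_state, c(FALSE, FALSE))
  expect_equal(got$states[1L], "R,T")
  # adding a second cell line's segments never clears a flag
  more <- rbind(segs, data.frame(chrom = "chr1", start = 5100L, end = 5200L,
                                 name = "TSS"))
  got2 <- chromatin_support(cl, more)
  expect_true(all(got2$has_T_state >= got$has_T_state))
  expect_equal(got2$has_TSS_state, c(FALSE, TRUE))
  expect_error(chromatin_support(cl, data.frame(chrom = "chr1", start = 1L,
                                                end = 2L, name = "XX")),
               "unknown chromatin state")
})

test_that("rnaseq support needs >= 10 reads within a single library", {
  cl <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  one <- coverage_track(data.frame(chrom = "chr1", start = 100L, end = 200L,
                                   value = 10))
  expect_true(rnaseq_support(cl, one))
  # 9 reads in each of 5 libraries never sum across libraries
  nine <- coverage_track(data.frame(chrom = "chr1", start = 100L, end = 200L,
                                    value = 9))
  expect_false(rnaseq_support(cl, rep(list(nine), 5L)))
  # split intervals within one library do sum
  split2 <- coverage_track(data.frame(chrom = "chr1", start = c(100L, 300L),
                                      end = c(200L, 400L), value = c(6, 5)))
  expect_true(rnaseq_support(cl, split2))
})

test_that("evidence matrix flags RefSeq-TSS clusters and sense/antisense", {
  genes <- make_gene("g1", "chr1", "+", c(1000L, 3000L), c(2000L, 4000L),
                     1500L, 3500L)
  clusters <- data.frame(cluster_id = c("c1", "c2", "c3"), chrom = "chr1",
                         start = c(1400L, 2100L, 500L),
                         end = c(1600L, 2900L, 700L))
  clusters <- classify_clusters(clusters, genes)
  peaks <- rbind(peak(2110L, 2120L, "+"), peak(650L, 660L, "-"))
  ev <- evidence_matrix(clusters, genes, peaks = peaks)
  # c1 touches the 5'UTR, c3 is fully inside the upstream flank
  expect_equal(ev$refseq_tss, c(TRUE, FALSE, TRUE))
  expect_equal(ev$orientation, c("none", "forward", "reverse"))
  # c2 reads forward like its + strand host: sense; c1/c3 are excluded
  expect_equal(ev$rel_orientation, c(NA, "sense", NA))
})
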