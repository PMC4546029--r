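# Alignment filters and EST clustering.

test_that("filter_unspliced applies the gap and mismatch rules", {
  psl <- rbind(
    # blocks [100,150),[200,250): gap 50 > 30, removed
    simple_psl_row("spliced", "chr1", 100L, 50L, gap_after = 50L,
                   second_len = 50L),
    # blocks [100,150),[160,210): gap 10, 2 % mismatches, retained
    simple_psl_row("ok", "chr1", 100L, 50L, gap_after = 10L,
                   second_len = 50L, mism = 2L),
    # 10 % mismatches, removed
    simple_psl_row("mm", "chr1", 500L, 100L, mism = 10L),
    # on an excluded haplotype chromosome
    simple_psl_row("hap", "chr1_hap1", 100L, 60L),
    # overlaps a NUMT
    simple_psl_row("numt", "chr1", 9000L, 80L))
  numts <- data.frame(chrom = "chr1", start = 9050L, end = 9300L)
  res <- filter_unspliced(psl, numts, "chr1_hap1")
  expect_equal(res$alignments$qName, "ok")
  expect_equal(unclass(res$report)[1:6],
               c(input = 5L, after_haplotype = 4L, after_gap = 3L,
                 after_mismatch = 2L, after_numt = 1L, unspliced_ests = 1L))
  # funnel is non-increasing
  expect_true(all(diff(unclass(res$report)[1:6]) <= 0L))
  # empty input gives a zeroed report
  empty <- filter_unspliced(psl[0, ])
  expect_equal(unname(unclass(empty$report)[["input"]]), 0L)
})

test_that("the summed-gap interpretation is available behind gap_mode", {
  # two gaps of 20 nt each: largest 20 (kept), summed 40 (removed)
  row <- uestr:::psl_row("e", "chr1", 100000L,
                         cbind(start = c(0L, 70L, 140L),
                               size = c(50L, 50L, 50L)))
  expect_equal(nrow(filter_unspliced(row)$alignments), 1L)
  expect_equal(nrow(filter_unspliced(
    row, config = uest_config(gap_mode = "summed"))$alignments), 0L)
})

test_that("filter funnel matches an independent per-alignment re-check", {
  set.seed(21)
  rows <- list()
  for (i in 1:400) {
    kind <- sample(c("clean", "gap", "mm", "numt", "hap"), 1L,
                   prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
    start <- sample(0:80000, 1L)
    len <- sample(60:300, 1L)
    rows[[i]] <- switch(kind,
      clean = simple_psl_row(paste0("e", i), "chr1", start, len),
      gap = simple_psl_row(paste0("e", i), "chr1", start, len,
                           gap_after = sample(31:500, 1L)),
      mm = simple_psl_row(paste0("e", i), "chr1", start, len,
                          mism = as.integer(ceiling(len * 0.08))),
      numt = simple_psl_row(paste0("e", i), "chr1",
                            90000L + sample(0:400, 1L), 50L),
      hap = simple_psl_row(paste0("e", i), "chr1_hap1", start, len))
  }
  psl <- do.call(rbind, rows)
  numts <- data.frame(chrom = "chr1", start = 90000L, end = 90500L)
  got <- filter_unspliced(psl, numts, "chr1_hap1")$report
  want <- oracle_filter_counts(psl, numts, "chr1_hap1")
  expect_equal(unclass(got)[names(want)], want)
})

test_that("cluster_ests joins at gap <= 30 and enforces the size floor", {
  ests <- data.frame(chrom = "chr1", start = c(0L, 120L, 220L),
                     end = c(100L, 200L, 300L), est_id = c("a", "b", "c"))
  cl <- cluster_ests(ests)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 0L)
  expect_equal(cl$end, 300L)
  expect_equal(cl$n_members, 3L)
  # gap of exactly 30 joins (end 100, next start 130)
  ests30 <- data.frame(chrom = "chr1", start = c(0L, 130L, 260L),
                       end = c(100L, 230L, 360L), est_id = c("a", "b", "c"))
  expect_equal(nrow(cluster_ests(ests30)), 1L)
  # gaps of 31 leave three singletons, none emitted
  ests31 <- data.frame(chrom = "chr1", start = c(0L, 131L, 262L),
                       end = c(100L, 231L, 362L), est_id = c("a", "b", "c"))
  expect_equal(nrow(cluster_ests(ests31)), 0L)
})

test_that("clustering equals the all-pairs union-find oracle", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(c(80L, 200L, 400L), 1L)
    ests <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample(0:200000, n, replace = TRUE),
      est_id = sprintf("e%04d", seq_len(n)))
    ests$end <- ests$start + sample(20:400, n, replace = TRUE)
    got <- cluster_ests(ests)
    want <- oracle_cluster(ests)
    expect_same_clusters(got, want)
  }
})

test_that("clustering is invariant to input order and clusters are maximal", {
  set.seed(41)
  n <- 300L
  ests <- data.frame(chrom = "chr1",
                     start = sample(0:100000, n, replace = TRUE),
                     est_id = sprintf("e%04d", seq_len(n)))
  ests$end <- ests$start + sample(20:300, n, replace = TRUE)
  base <- cluster_ests(ests)
  for (rep in 1:3) {
    perm <- ests[sample.int(n), ]
    expect_equal(cluster_ests(perm), base)
  }
  # hull containment and inter-cluster separation > 30 nt
  members <- strsplit(base$members, ",", fixed = TRUE)
  for (k in seq_len(nrow(base))) {
    m <- ests[ests$est_id %in% members[[k]], ]
    expect_true(all(m$start >= base$start[k] & m$end <= base$end[k]))
    expect_equal(min(m$start), base$start[k])
    expect_equal(max(m$end), base$end[k])
  }
  if (nrow(base) > 1L) {
    gaps <- base$start[-1L] - base$end[-nrow(base)]
    expect_true(all(gaps > 30L))
  }
})
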