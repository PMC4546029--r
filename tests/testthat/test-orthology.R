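# Chain lifting and cross-species pairing.

test_that("lift_interval handles identity, offset and gap chains", {
  ident <- make_chain(list(c(1000L, 0L, 0L)), t_name = "chr1", q_name = "chr1")
  got <- lift_interval(list(chrom = "chr1", start = 100L, end = 200L),
                       list(ident))
  expect_equal(got[c("chrom", "start", "end")],
               list(chrom = "chr1", start = 100L, end = 200L))
  expect_equal(got$mapped_frac, 1)
  # single block [0,500) -> [2000,2500): constant offset
  off <- make_chain(list(c(500L, 0L, 0L)), q_start = 2000L)
  expect_equal(lift_interval(list(chrom = "chrA", start = 100L, end = 150L),
                             list(off))[c("start", "end")],
               list(start = 2100L, end = 2150L))
  # an interval straddling a 50-nt target-side gap: all source bases map,
  # the target span grows by 50
  gapped <- make_chain(list(c(100L, 0L, 50L), c(100L, 0L, 0L)))
  got <- lift_interval(list(chrom = "chrA", start = 50L, end = 150L),
                       list(gapped))
  expect_equal(got$mapped_frac, 1)
  expect_equal(got$end - got$start, 150L)
  # an interval entirely inside a source gap maps nowhere
  srcgap <- make_chain(list(c(100L, 200L, 0L), c(100L, 0L, 0L)))
  expect_null(lift_interval(list(chrom = "chrA", start = 120L, end = 180L),
                            list(srcgap)))
  # partial overlap with a source gap fails the 0.95 fraction rule
  expect_null(lift_interval(list(chrom = "chrA", start = 50L, end = 150L),
                            list(srcgap)))
  expect_equal(lift_interval(list(chrom = "chrA", start = 50L, end = 150L),
                             list(srcgap), min_mapped_frac = 0.5)$mapped_frac,
               0.5)
  # ambiguous placement: two chains above threshold reject the lift
  two <- list(make_chain(list(c(1000L, 0L, 0L)), chain_id = "1"),
              make_chain(list(c(1000L, 0L, 0L)), q_start = 5000L,
                         chain_id = "2"))
  expect_null(lift_interval(list(chrom = "chrA", start = 10L, end = 60L), two))
})

test_that("minus-strand chains report forward target coordinates", {
  ch <- make_chain(list(c(500L, 0L, 0L)), q_strand = "-", q_start = 0L,
                   q_size = 10000L)
  got <- lift_interval(list(chrom = "chrA", start = 100L, end = 150L),
                       list(ch))
  # q-strand coordinates [100,150) count from the reversed sequence
  expect_equal(got$start, 10000L - 150L)
  expect_equal(got$end, 10000L - 100L)
})

test_that("lifting equals the per-base brute-force mapper on random chains", {
  set.seed(121)
  for (rep in 1:60) {
    chains <- list(random_chain(q_strand = sample(c("+", "-"), 1L)))
    span <- c(chains[[1L]]$t_start, chains[[1L]]$t_end)
    s <- sample(max(0L, span[1L] - 50L):(span[2L] + 20L), 1L)
    e <- s + sample(10:300, 1L)
    iv <- list(chrom = "chrA", start = s, end = e)
    frac <- sample(c(0.5, 0.8, 0.95, 1), 1L)
    got <- lift_interval(iv, chains, frac)
    want <- oracle_lift(iv, chains, frac)
    if (is.null(want)) expect_null(got) else
      expect_equal(got, want)
  }
})

test_that("identity round-trips and chain composition contain the original", {
  ident_ab <- make_chain(list(c(5000L, 0L, 0L)), t_name = "chrA",
                         q_name = "chrB")
  ident_ba <- make_chain(list(c(5000L, 0L, 0L)), t_name = "chrB",
                         q_name = "chrA")
  set.seed(131)
  for (rep in 1:20) {
    s <- sample(0:4000, 1L); e <- s + sample(1:900, 1L)
    there <- lift_interval(list(chrom = "chrA", start = s, end = e),
                           list(ident_ab))
    back <- lift_interval(there, list(ident_ba))
    expect_equal(back[c("start", "end")], list(start = s, end = e))
  }
})

test_that("pair_orthologs unions both directions and flags classes", {
  a <- data.frame(cluster_id = c("a1", "a2"), chrom = "chrA",
                  start = c(100L, 3000L), end = c(200L, 3300L),
                  class = c("TIN", "TEX"), stringsAsFactors = FALSE)
  b <- data.frame(cluster_id = c("b1", "b2"), chrom = "chrB",
                  start = c(150L, 3100L), end = c(250L, 3400L),
                  class = c("TIN", "IGR"), stringsAsFactors = FALSE)
  ident_ab <- list(make_chain(list(c(10000L, 0L, 0L)), t_name = "chrA",
                              q_name = "chrB"))
  ident_ba <- list(make_chain(list(c(10000L, 0L, 0L)), t_name = "chrB",
                              q_name = "chrA"))
  pairs <- pair_orthologs(a, b, ident_ab, ident_ba)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$detected_by, c("both", "both"))
  expect_equal(pairs$same_class, c(TRUE, FALSE))
  # a pair only reachable through the B->A chains is still emitted
  no_ab <- list(make_chain(list(c(10L, 0L, 0L)), t_name = "chrA",
                           q_name = "chrB"))
  pairs2 <- pair_orthologs(a, b, no_ab, ident_ba)
  expect_equal(nrow(pairs2), 2L)
  expect_true(all(pairs2$detected_by == "B->A"))
  # union is a superset of each directional set
  expect_true(all(paste(pairs2$cluster_a, pairs2$cluster_b) %in%
                    paste(pairs$cluster_a, pairs$cluster_b)))
  summ <- conservation_summary(pairs, a, b)
  expect_equal(unname(summ["n_pairs"]), 2L)
  expect_equal(unname(summ["n_distinct_a"]), 2L)
  expect_equal(unname(summ["n_same_class"]), 1L)
  expect_equal(unname(summ["n_unpaired_a"]), 0L)
  empty <- conservation_summary(pairs[0, ], a, b)
  expect_equal(unname(empty["n_unpaired_a"]), nrow(a))
  expect_equal(unname(empty["n_unpaired_b"]), nrow(b))
})

test_that("conservation_summary counts distinct clusters per genome", {
  pairs <- data.frame(cluster_a = c("a1", "a1", "a2"),
                      cluster_b = c("b1", "b2", "b3"),
                      detected_by = "both", same_class = c(TRUE, FALSE, TRUE))
  a <- data.frame(cluster_id = c("a1", "a2", "a3"))
  b <- data.frame(cluster_id = c("b1", "b2", "b3"))
  s <- conservation_summary(pairs, a, b)
  expect_equal(unname(s["n_distinct_a"]), 2L)
  expect_equal(unname(s["n_distinct_b"]), 3L)
  expect_lte(s[["n_distinct_a"]], s[["n_pairs"]])
  expect_equal(unname(s["n_unpaired_a"]), 1L)
})

test_that("planted two-genome orthologs are recovered exactly", {
  scn <- generate_scenario(scenario_config(seed = 17, n_genes = 4, n_igr = 4,
                                           two_genomes = TRUE,
                                           n_ortholog = 6L))
  res <- run_all(scn$files, withr::local_tempdir(),
                 excluded_chroms = scn$excluded_chroms)
  truth <- scn$truth$clusters
  want_a <- truth[truth$genome == "A" & !is.na(truth$ortholog), ]
  expect_equal(nrow(res$orthologs), nrow(want_a))
  expect_true(all(res$orthologs$same_class))
  expect_true(all(res$orthologs$detected_by == "both"))
  # the paired A clusters are exactly the planted ortholog intervals
  got_a <- res$classes[match(res$orthologs$cluster_a, res$classes$cluster_id), ]
  expect_setequal(paste(got_a$chrom, got_a$start, got_a$end),
                  paste(want_a$chrom, want_a$start, want_a$end))
})
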