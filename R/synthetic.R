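# Synthetic two-genome scenario generator with planted ground truth.
#
# The generator emulates the statistical structure of the real inputs --
# spliced vs unspliced PSL alignments, nested gene components, stranded TSS
# peaks at cluster ends, state-labeled chromatin segments, colinear chain
# blocks with indels, per-base conservation elevated over exons -- while
# keeping every planted cluster geometrically unambiguous for its class:
# deciding overlaps exceed the 20-nt rule by a wide margin, distinct plants
# are separated by far more than the 30-nt join distance, and intergenic
# plants sit well outside the 5-kb gene flanks.

# run code under a seed without disturbing global random state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the synthetic generator
#'
#' All randomness flows from `seed`; the same configuration always yields
#' a byte-identical bundle.  Exon and intron lengths are drawn log-normal
#' (parameters below) and clamped to the minimum sizes the planted-class
#' geometry needs.  Decoy counts plant alignments that each violate
#' exactly one filter; the conversion fractions instead corrupt planted
#' cluster members in place (a spliced conversion opens a >30 nt gap, a
#' mismatch conversion raises the mismatch rate to 8 %).
#'
#' @param seed integer seed; fully determines the bundle.
#' @param n_chromosomes number of chromosomes; gene bundles are dealt
#'   round-robin.
#' @param chrom_length_nt fixed chromosome length, or `NULL` to size each
#'   chromosome to its layout.  Too small a fixed length is an
#'   "infeasible packing" error.
#' @param n_genes number of fully planted genes; each carries one cluster
#'   of every genic class (TEX, TIN, 5PIN, 3PIN, rI, 5R, 3R, UT, DT).
#' @param n_igr number of intergenic plants (> 5 kb from every gene).
#' @param plant_no_class also plant one deliberately ambiguous cluster
#'   (two introns plus the exon between them) on an extra gene.
#' @param two_genomes also emit genome B, related to A by indel-bearing
#'   chains, with `n_ortholog` planted ortholog clusters.
#' @param n_ortholog number of genome-A plants mirrored into genome B.
#' @param n_uarna number of 3R plants given unambiguous CAGE orientation
#'   (these are the true CAGE uaRNAs); must not exceed `n_genes`.
#' @param ests_per_cluster inclusive range of member ESTs per plant.
#' @param exon_meanlog,exon_sdlog,intron_meanlog,intron_sdlog log-normal
#'   parameters of exon/intron lengths (nt).
#' @param orientation_probs sampling weights for the planted orientation
#'   of non-3R clusters (`forward, reverse, none, bidirectional`).
#' @param n_cell_types number of per-cell-type CAGE peak sets.
#' @param cage_jitter_nt placement jitter of TSS peaks inside the 84-nt
#'   end window.
#' @param p_chromatin_T,p_chromatin_TSS per-cluster probability of a
#'   transcribed-state / TSS-state chromatin segment.
#' @param p_rnaseq_support per-cluster probability of >= 10 reads in
#'   library 1 (unsupported clusters get < 10 reads in every library).
#' @param n_gap_decoys,n_mismatch_decoys,n_numt_decoys,n_hap_decoys
#'   planted filter-violating alignments (spliced gap > 30 nt, > 5 %
#'   mismatches, NUMT overlap, alternative-haplotype chromosome).
#' @param spliced_decoy_frac,mismatch_decoy_frac per-EST conversion
#'   probabilities applied to planted cluster members.
#' @param chain_indel_rate,chain_indel_max per-safe-gap indel probability
#'   and maximum indel length (nt) of the A/B chains.
#' @param cons_base,cons_exon_elevation,cons_noise_sd,cons_step_nt
#'   conservation track: baseline score, added elevation over exonic
#'   bases, per-window Gaussian noise, window width.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_chromosomes = 1L,
                            chrom_length_nt = NULL,
                            n_genes = 4L,
                            n_igr = n_genes,
                            plant_no_class = FALSE,
                            two_genomes = FALSE,
                            n_ortholog = 0L,
                            n_uarna = 0L,
                            ests_per_cluster = c(3L, 6L),
                            exon_meanlog = log(320), exon_sdlog = 0.08,
                            intron_meanlog = log(1000), intron_sdlog = 0.12,
                            orientation_probs = c(forward = 0.35, reverse = 0.3,
                                                  none = 0.25, bidirectional = 0.1),
                            n_cell_types = 6L,
                            cage_jitter_nt = 5L,
                            p_chromatin_T = 0.6,
                            p_chromatin_TSS = 0.3,
                            p_rnaseq_support = 0.8,
                            n_gap_decoys = 0L, n_mismatch_decoys = 0L,
                            n_numt_decoys = 0L, n_hap_decoys = 0L,
                            spliced_decoy_frac = 0, mismatch_decoy_frac = 0,
                            chain_indel_rate = 0.5, chain_indel_max = 400L,
                            cons_base = 0.1, cons_exon_elevation = 0.3,
                            cons_noise_sd = 0.02, cons_step_nt = 20L) {
  cfg <- as.list(environment())
  rates <- c(cfg$spliced_decoy_frac, cfg$mismatch_decoy_frac,
             cfg$chain_indel_rate, cfg$p_chromatin_T, cfg$p_chromatin_TSS,
             cfg$p_rnaseq_support)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (cfg$n_uarna > cfg$n_genes)
    stop("n_uarna cannot exceed the number of 3R plants (one per gene)")
  if (cfg$ests_per_cluster[1L] < 3L)
    stop("planted clusters need at least 3 member ESTs")
  if (cfg$two_genomes && cfg$n_ortholog < 1L && cfg$n_genes > 0L)
    cfg$n_ortholog <- 1L
  structure(cfg, class = "scenario_config")
}

# one planted gene: four exons, three introns, CDS leaving a 120-nt 5'UTR
# and a >= 200-nt 3'UTR, plus one plant of every genic class with margins
# far beyond the 20-nt overlap rule and the 30-nt join distance
plant_gene <- function(gene_id, chrom, gs, strand, elen, ilen) {
  es <- integer(4); ee <- integer(4)
  pos <- gs
  for (k in 1:4) {
    es[k] <- pos; ee[k] <- pos + elen[k]
    pos <- ee[k] + if (k < 4L) ilen[k] else 0L
  }
  ge <- ee[4L]
  if (strand == "+") {
    cds_start <- gs + 120L; cds_end <- es[4L] + 150L
  } else {
    cds_start <- ee[1L] - 150L; cds_end <- ge - 120L
  }
  gene <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                     tx_start = gs, tx_end = ge, cds_start = cds_start,
                     cds_end = cds_end, exon_count = 4L, coding = TRUE,
                     stringsAsFactors = FALSE)
  gene$exon_starts <- list(es); gene$exon_ends <- list(ee)
  p <- if (strand == "+") {
    list(TEX = c(es[2L] + 30L, es[2L] + 180L),
         TIN = c(ee[1L] + 200L, ee[1L] + 500L),
         `5PIN` = c(ee[1L] - 60L, ee[1L] + 100L),
         `3PIN` = c(es[4L] - 100L, es[4L] + 60L),
         rI = c(ee[2L] - 40L, es[3L] + 40L),
         `5R` = c(gs - 80L, gs + 80L),
         `3R` = c(ge - 80L, ge + 80L),
         UT = c(gs - 3000L, gs - 2800L),
         DT = c(ge + 2800L, ge + 3000L))
  } else {
    list(TEX = c(ee[3L] - 180L, ee[3L] - 30L),
         TIN = c(es[4L] - 500L, es[4L] - 200L),
         `5PIN` = c(es[4L] - 100L, es[4L] + 60L),
         `3PIN` = c(ee[1L] - 60L, ee[1L] + 100L),
         rI = c(ee[2L] - 40L, es[3L] + 40L),
         `5R` = c(ge - 80L, ge + 80L),
         `3R` = c(gs - 80L, gs + 80L),
         UT = c(ge + 2800L, ge + 3000L),
         DT = c(gs - 3000L, gs - 2800L))
  }
  plants <- data.frame(chrom = chrom, start = vapply(p, `[[`, integer(1), 1L),
                       end = vapply(p, `[[`, integer(1), 2L),
                       class = names(p), gene_id = gene_id,
                       stringsAsFactors = FALSE)
  list(gene = gene, plants = plants, gene_end = ge)
}

draw_gene_lengths <- function() {
  elen <- pmin(500L, pmax(c(250L, 260L, 260L, 350L),
                          as.integer(round(stats::rlnorm(4, log(320), 0.08)))))
  ilen <- pmin(1500L, pmax(800L, as.integer(round(stats::rlnorm(3, log(1000), 0.12)))))
  list(elen = elen, ilen = ilen)
}

# single-block PSL row; blocks is a (start, size) matrix
psl_row <- function(qname, tname, tsize, blocks, mism = 0L) {
  sizes <- blocks[, "size"]; starts <- blocks[, "start"]
  qsize <- sum(sizes)
  ends <- starts + sizes
  gaps <- if (nrow(blocks) > 1L) starts[-1L] - ends[-nrow(blocks)] else integer(0)
  data.frame(matches = qsize - mism, misMatches = mism, repMatches = 0L,
             nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
             tNumInsert = sum(gaps > 0L), tBaseInsert = sum(gaps),
             strand = "+", qName = qname, qSize = qsize, qStart = 0L,
             qEnd = qsize, tName = tname, tSize = tsize,
             tStart = starts[1L], tEnd = ends[length(ends)],
             blockCount = nrow(blocks),
             blockSizes = paste0(paste(sizes, collapse = ","), ","),
             qStarts = paste0(paste(cumsum(c(0L, sizes[-length(sizes)])),
                                    collapse = ","), ","),
             tStarts = paste0(paste(starts, collapse = ","), ","),
             stringsAsFactors = FALSE)
}

# >= 3 staggered overlapping single-block ESTs whose union is [s, e)
plant_ests <- function(prefix, chrom, tsize, s, e, n) {
  w <- e - s
  len <- max(40L, min(w, as.integer(round(w * 0.6))))
  starts <- s + as.integer(round(seq(0L, w - len, length.out = n)))
  do.call(rbind, lapply(seq_len(n), function(k)
    psl_row(sprintf("%s_%02d", prefix, k), chrom, tsize,
            cbind(start = starts[k], size = len))))
}

#' Generate a synthetic scenario bundle
#'
#' Lays out `n_genes` four-exon genes (alternating strands) plus
#' intergenic and decoy zones on each chromosome, plants one cluster of
#' every genic class per gene and `n_igr` intergenic clusters, emits the
#' member ESTs as PSL plus CAGE peaks (global and per cell type),
#' chromatin segments, RNA-seq bedGraph libraries, a conservation wiggle
#' track and, for two-genome scenarios, genome B (genome A transformed
#' through indel-bearing chains, with `n_ortholog` mirrored plants) and
#' the chain files in both directions.  Ground truth for every planted
#' cluster and alignment is returned and written alongside.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created; default a fresh tempdir).
#' @return An object of class `uest_scenario`: list with `dir`, `files`
#'   (named paths), `truth` (list of data.frames: `clusters`, `funnel_a`,
#'   `decoys`), `excluded_chroms`, `chrom_sizes_a`, `chrom_sizes_b`,
#'   `config`.
#' @examples
#' scn <- generate_scenario(scenario_config(seed = 1, n_genes = 2))
#' scn$truth$clusters[, c("chrom", "start", "end", "class")]
#' @export
generate_scenario <- function(config = scenario_config(),
                              out_dir = tempfile("uest_scenario_")) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, generate_scenario_impl(config, out_dir))
}

generate_scenario_impl <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  genes <- list(); plants <- list(); safe_gaps <- list(); numts <- list()
  decoy_rows <- list(); decoy_kind <- character(0)
  chrom_len <- setNames(integer(length(chroms)), chroms)
  # provisional tSize for PSL rows, patched after layout
  TS <- 1L

  gene_chrom <- if (cfg$n_genes > 0L)
    chroms[((seq_len(cfg$n_genes) - 1L) %% length(chroms)) + 1L] else character(0)
  igr_chrom <- if (cfg$n_igr > 0L)
    chroms[((seq_len(cfg$n_igr) - 1L) %% length(chroms)) + 1L] else character(0)

  gid <- 0L
  for (chr in chroms) {
    cursor <- 10000L
    n_here <- sum(gene_chrom == chr) + ifelse(cfg$plant_no_class && chr == chroms[1L], 1L, 0L)
    for (k in seq_len(n_here)) {
      gid <- gid + 1L
      is_nc <- cfg$plant_no_class && chr == chroms[1L] && k == n_here
      gs <- cursor + 5000L
      L <- draw_gene_lengths()
      strand <- if (gid %% 2L == 1L) "+" else "-"
      pg <- plant_gene(sprintf("g%03d", gid), chr, gs, strand, L$elen, L$ilen)
      genes[[length(genes) + 1L]] <- pg$gene
      if (is_nc) {
        # ambiguous plant: two introns plus the exon between them
        es <- pg$gene$exon_starts[[1L]]; ee <- pg$gene$exon_ends[[1L]]
        plants[[length(plants) + 1L]] <- data.frame(
          chrom = chr, start = es[2L] - 100L, end = ee[2L] + 100L,
          class = "NO_CLASS", gene_id = pg$gene$gene_id,
          stringsAsFactors = FALSE)
      } else {
        plants[[length(plants) + 1L]] <- pg$plants
      }
      flank_end <- pg$gene_end + 5000L
      safe_gaps[[length(safe_gaps) + 1L]] <-
        data.frame(chrom = chr, start = flank_end + 200L,
                   end = flank_end + 1300L, stringsAsFactors = FALSE)
      cursor <- flank_end + 1500L
    }
    n_igr_here <- sum(igr_chrom == chr)
    if (n_igr_here > 0L) {
      izs <- cursor + 4000L
      for (k in seq_len(n_igr_here)) {
        s <- izs + (k - 1L) * 600L
        plants[[length(plants) + 1L]] <- data.frame(
          chrom = chr, start = s, end = s + 200L, class = "IGR",
          gene_id = "", stringsAsFactors = FALSE)
      }
      cursor <- izs + n_igr_here * 600L + 1000L
    }
    if (chr == chroms[1L]) {
      # decoy zone: NUMT regions and filter-violating alignments
      dz <- cursor + 1000L
      for (k in seq_len(cfg$n_numt_decoys)) {
        p <- dz + (k - 1L) * 800L
        numts[[length(numts) + 1L]] <- data.frame(chrom = chr, start = p,
                                                  end = p + 300L)
        decoy_rows[[length(decoy_rows) + 1L]] <-
          psl_row(sprintf("numt_decoy_%03d", k), chr, TS,
                  cbind(start = p + 50L, size = 100L))
        decoy_kind <- c(decoy_kind, "numt")
      }
      dz <- dz + max(0L, cfg$n_numt_decoys) * 800L + 1000L
      for (k in seq_len(cfg$n_gap_decoys)) {
        p <- dz + (k - 1L) * 800L
        decoy_rows[[length(decoy_rows) + 1L]] <-
          psl_row(sprintf("gap_decoy_%03d", k), chr, TS,
                  cbind(start = c(p, p + 260L), size = c(60L, 60L)))
        decoy_kind <- c(decoy_kind, "gap")
      }
      dz <- dz + max(0L, cfg$n_gap_decoys) * 800L + 1000L
      for (k in seq_len(cfg$n_mismatch_decoys)) {
        p <- dz + (k - 1L) * 800L
        decoy_rows[[length(decoy_rows) + 1L]] <-
          psl_row(sprintf("mm_decoy_%03d", k), chr, TS,
                  cbind(start = p, size = 100L), mism = 10L)
        decoy_kind <- c(decoy_kind, "mismatch")
      }
      cursor <- dz + max(0L, cfg$n_mismatch_decoys) * 800L + 1000L
    }
    chrom_len[chr] <- cursor + 10000L
  }
  if (!is.null(cfg$chrom_length_nt)) {
    if (any(chrom_len > cfg$chrom_length_nt))
      stop(sprintf("infeasible packing: layout needs %d nt but chrom_length_nt is %d",
                   max(chrom_len), cfg$chrom_length_nt))
    chrom_len[] <- as.integer(cfg$chrom_length_nt)
  }
  genes <- if (length(genes)) do.call(rbind, genes) else empty_genepred()
  plants <- do.call(rbind, plants)
  plants$plant_id <- sprintf("plant%04d", seq_len(nrow(plants)))
  rownames(plants) <- NULL

  # planted orientations; the first n_uarna 3R plants are forced
  # forward/reverse (true CAGE uaRNAs), the other 3R plants get none
  ori <- sample(names(cfg$orientation_probs), nrow(plants), replace = TRUE,
                prob = cfg$orientation_probs)
  r3 <- which(plants$class == "3R")
  if (cfg$n_uarna > length(r3))
    stop("n_uarna exceeds the number of 3R plants")
  ori[r3] <- "none"
  if (cfg$n_uarna > 0L)
    ori[r3[seq_len(cfg$n_uarna)]] <- rep(c("forward", "reverse"),
                                         length.out = cfg$n_uarna)
  plants$orientation <- ori

  # per-cluster evidence truth
  plants$breadth <- 0L
  orientable <- plants$orientation %in% c("forward", "reverse")
  if (cfg$n_cell_types > 0L)
    plants$breadth[orientable] <- sample(seq_len(cfg$n_cell_types),
                                         sum(orientable), replace = TRUE)
  plants$has_T <- runif(nrow(plants)) < cfg$p_chromatin_T
  plants$has_TSS <- runif(nrow(plants)) < cfg$p_chromatin_TSS
  plants$rnaseq_supported <- runif(nrow(plants)) < cfg$p_rnaseq_support
  plants$is_uarna <- plants$class == "3R" & orientable
  plants$is_uarna_chromatin <- plants$class == "3R" & plants$has_TSS

  # ortholog selection
  plants$ortholog <- NA_character_
  if (cfg$two_genomes && cfg$n_ortholog > 0L) {
    if (cfg$n_ortholog > nrow(plants))
      stop("n_ortholog exceeds the number of planted clusters")
    sel <- sort(sample(seq_len(nrow(plants)), cfg$n_ortholog))
    plants$ortholog[sel] <- sprintf("op%04d", seq_along(sel))
  }

  # member ESTs for every plant, with optional in-place corruption
  n_members <- sample(seq(cfg$ests_per_cluster[1L], cfg$ests_per_cluster[2L]),
                      nrow(plants), replace = TRUE)
  est_rows <- vector("list", nrow(plants))
  conv_spliced <- 0L; conv_mm <- 0L
  for (i in seq_len(nrow(plants))) {
    rows <- plant_ests(plants$plant_id[i], plants$chrom[i], TS,
                       plants$start[i], plants$end[i], n_members[i])
    for (j in seq_len(nrow(rows))) {
      if (cfg$spliced_decoy_frac > 0 && runif(1) < cfg$spliced_decoy_frac) {
        st <- rows$tStart[j]; len <- rows$qSize[j]
        rows[j, ] <- psl_row(rows$qName[j], rows$tName[j], TS,
                             cbind(start = c(st, st + len + 200L),
                                   size = c(len, 60L)))
        conv_spliced <- conv_spliced + 1L
      } else if (cfg$mismatch_decoy_frac > 0 && runif(1) < cfg$mismatch_decoy_frac) {
        mism <- as.integer(ceiling(rows$qSize[j] * 0.08))
        rows$misMatches[j] <- mism
        rows$matches[j] <- rows$qSize[j] - mism
        conv_mm <- conv_mm + 1L
      }
    }
    est_rows[[i]] <- rows
  }
  plants$n_ests <- n_members
  psl_a <- do.call(rbind, c(est_rows, decoy_rows))
  if (is.null(psl_a)) psl_a <- empty_psl()

  # haplotype decoys live on an excluded chromosome
  hap_chrom <- paste0(chroms[1L], "_hap1")
  if (cfg$n_hap_decoys > 0L) {
    hap <- do.call(rbind, lapply(seq_len(cfg$n_hap_decoys), function(k)
      psl_row(sprintf("hap_decoy_%03d", k), hap_chrom, 50000L,
              cbind(start = 1000L + (k - 1L) * 500L, size = 100L))))
    psl_a <- rbind(psl_a, hap)
  }
  psl_a$tSize <- ifelse(psl_a$tName == hap_chrom, 50000L,
                        chrom_len[psl_a$tName])

  # CAGE peaks: a ~10-nt stranded peak just inside the relevant 84-nt
  # end window of each oriented plant
  peak_fw <- function(i) {
    j <- sample.int(cfg$cage_jitter_nt + 1L, 1L) - 1L
    data.frame(chrom = plants$chrom[i], start = plants$start[i] + 5L + j,
               end = plants$start[i] + 15L + j,
               name = paste0("pfw_", plants$plant_id[i]), score = 1L,
               strand = "+", stringsAsFactors = FALSE)
  }
  peak_rv <- function(i) {
    j <- sample.int(cfg$cage_jitter_nt + 1L, 1L) - 1L
    data.frame(chrom = plants$chrom[i], start = plants$end[i] - 15L - j,
               end = plants$end[i] - 5L - j,
               name = paste0("prv_", plants$plant_id[i]), score = 1L,
               strand = "-", stringsAsFactors = FALSE)
  }
  peaks <- list(); peak_owner <- character(0)
  for (i in seq_len(nrow(plants))) {
    o <- plants$orientation[i]
    if (o %in% c("forward", "bidirectional")) {
      peaks[[length(peaks) + 1L]] <- peak_fw(i)
      peak_owner <- c(peak_owner, plants$plant_id[i])
    }
    if (o %in% c("reverse", "bidirectional")) {
      peaks[[length(peaks) + 1L]] <- peak_rv(i)
      peak_owner <- c(peak_owner, plants$plant_id[i])
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))

  # per-cell-type sets: each oriented plant's peaks appear in `breadth`
  # randomly chosen cell types
  cell_sets <- replicate(cfg$n_cell_types, integer(0), simplify = FALSE)
  if (cfg$n_cell_types > 0L) {
    for (i in which(orientable)) {
      cells <- sample.int(cfg$n_cell_types, plants$breadth[i])
      rows <- which(peak_owner == plants$plant_id[i])
      for (cl in cells) cell_sets[[cl]] <- c(cell_sets[[cl]], rows)
    }
  }

  # chromatin segments over flagged plants, two nominal cell lines
  segs <- list()
  for (i in seq_len(nrow(plants))) {
    if (plants$has_TSS[i])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = plants$chrom[i], start = plants$start[i] + 2L,
        end = plants$start[i] + 30L, name = "TSS", stringsAsFactors = FALSE)
    if (plants$has_T[i])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = plants$chrom[i], start = plants$start[i] + 10L,
        end = pmin(plants$end[i], plants$start[i] + 110L), name = "T",
        stringsAsFactors = FALSE)
  }
  # low-activity background segments between features
  segs[[length(segs) + 1L]] <- data.frame(chrom = chroms[1L], start = 0L,
                                          end = 5000L, name = "R",
                                          stringsAsFactors = FALSE)
  segs <- do.call(rbind, segs)

  # RNA-seq libraries: read counts per cluster interval
  lib1 <- list(); lib2 <- list()
  for (i in seq_len(nrow(plants))) {
    if (plants$rnaseq_supported[i]) {
      lib1[[length(lib1) + 1L]] <- data.frame(
        chrom = plants$chrom[i], start = plants$start[i], end = plants$end[i],
        value = 12, stringsAsFactors = FALSE)
    } else {
      lib1[[length(lib1) + 1L]] <- data.frame(
        chrom = plants$chrom[i], start = plants$start[i], end = plants$end[i],
        value = 4, stringsAsFactors = FALSE)
      lib2[[length(lib2) + 1L]] <- data.frame(
        chrom = plants$chrom[i], start = plants$start[i], end = plants$end[i],
        value = 5, stringsAsFactors = FALSE)
    }
  }
  mk_track <- function(l) {
    df <- if (length(l)) do.call(rbind, l) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 value = numeric(0))
    coverage_track(df)
  }
  track1 <- mk_track(lib1); track2 <- mk_track(lib2)

  # conservation: windows of cons_step_nt, baseline plus elevation scaled
  # by the exonic fraction of the window, plus Gaussian noise
  exons <- if (nrow(genes)) data.frame(
    chrom = rep(genes$chrom, genes$exon_count),
    start = unlist(genes$exon_starts), end = unlist(genes$exon_ends)) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
  cons <- list()
  for (chr in chroms) {
    starts <- seq(0L, chrom_len[chr] - cfg$cons_step_nt, by = cfg$cons_step_nt)
    win <- data.frame(chrom = chr, start = starts,
                      end = starts + cfg$cons_step_nt)
    frac <- rep(0, nrow(win))
    ex <- exons[exons$chrom == chr, , drop = FALSE]
    if (nrow(ex)) {
      hits <- overlap_pairs(win, ex)
      if (nrow(hits)) {
        w <- overlap_width(win$start[hits$a], win$end[hits$a],
                           ex$start[hits$b], ex$end[hits$b])
        agg <- rowsum(w, hits$a)
        frac[as.integer(rownames(agg))] <- agg[, 1L] / cfg$cons_step_nt
      }
    }
    v <- cfg$cons_base + cfg$cons_exon_elevation * frac +
      rnorm(nrow(win), 0, cfg$cons_noise_sd)
    win$value <- round(pmin(1, pmax(0, v)), 4L)
    cons[[chr]] <- win
  }
  cons <- coverage_track(do.call(rbind, cons))

  # ---- genome B ----
  files <- list()
  chrom_len_b <- chrom_len
  truth_b <- NULL
  if (cfg$two_genomes) {
    safe_gaps <- do.call(rbind, safe_gaps)
    chains_ab <- list(); chains_ba <- list()
    events_by_chrom <- list()
    for (ci in seq_along(chroms)) {
      chr <- chroms[ci]
      g <- safe_gaps[safe_gaps$chrom == chr, , drop = FALSE]
      ev <- list()
      for (k in seq_len(nrow(g))) {
        if (runif(1) >= cfg$chain_indel_rate) next
        len <- sample(50:cfg$chain_indel_max, 1L)
        type <- if (runif(1) < 0.5) "del" else "ins"
        if (type == "del" && g$end[k] - g$start[k] < len + 100L) type <- "ins"
        ev[[length(ev) + 1L]] <- data.frame(pos = g$start[k] + 50L,
                                            type = type, len = len,
                                            stringsAsFactors = FALSE)
      }
      ev <- if (length(ev)) do.call(rbind, ev) else
        data.frame(pos = integer(0), type = character(0), len = integer(0))
      ev <- ev[order(ev$pos), , drop = FALSE]
      events_by_chrom[[chr]] <- ev
      # chain blocks
      blocks <- list(); prev <- 0L
      for (k in seq_len(nrow(ev))) {
        blocks[[length(blocks) + 1L]] <-
          c(ev$pos[k] - prev,
            if (ev$type[k] == "del") ev$len[k] else 0L,
            if (ev$type[k] == "ins") ev$len[k] else 0L)
        prev <- ev$pos[k] + if (ev$type[k] == "del") ev$len[k] else 0L
      }
      blocks[[length(blocks) + 1L]] <- c(chrom_len[chr] - prev, 0L, 0L)
      b <- do.call(rbind, blocks)
      colnames(b) <- c("size", "dt", "dq")
      len_b <- sum(b[, "size"]) + sum(b[, "dq"])
      chrom_len_b[chr] <- len_b
      chains_ab[[ci]] <- list(score = sum(b[, "size"]), t_name = chr,
                              t_size = chrom_len[chr], t_strand = "+",
                              t_start = 0L, t_end = chrom_len[chr],
                              q_name = chr, q_size = len_b, q_strand = "+",
                              q_start = 0L, q_end = len_b,
                              chain_id = as.character(ci), blocks = b)
      b2 <- b[, c("size", "dq", "dt"), drop = FALSE]
      colnames(b2) <- c("size", "dt", "dq")
      chains_ba[[ci]] <- list(score = sum(b[, "size"]), t_name = chr,
                              t_size = len_b, t_strand = "+",
                              t_start = 0L, t_end = len_b,
                              q_name = chr, q_size = chrom_len[chr],
                              q_strand = "+", q_start = 0L,
                              q_end = chrom_len[chr],
                              chain_id = as.character(ci), blocks = b2)
    }
    a2b <- function(chr, x) {
      ev <- events_by_chrom[[chr]]
      if (nrow(ev) == 0L) return(x)
      delta <- ifelse(ev$type == "ins", ev$len, -ev$len)
      cum <- cumsum(delta)
      # shift applies to positions at/after pos (del: after pos + len,
      # but planted features never sit inside a deleted segment)
      idx <- findInterval(x, ev$pos + ifelse(ev$type == "del", ev$len, 0L))
      x + ifelse(idx > 0L, cum[pmax(idx, 1L)], 0L)
    }
    genes_b <- genes
    for (i in seq_len(nrow(genes_b))) {
      chr <- genes_b$chrom[i]
      genes_b$tx_start[i] <- a2b(chr, genes_b$tx_start[i])
      genes_b$tx_end[i] <- a2b(chr, genes_b$tx_end[i])
      genes_b$cds_start[i] <- a2b(chr, genes_b$cds_start[i])
      genes_b$cds_end[i] <- a2b(chr, genes_b$cds_end[i])
      genes_b$exon_starts[[i]] <- a2b(chr, genes_b$exon_starts[[i]])
      genes_b$exon_ends[[i]] <- a2b(chr, genes_b$exon_ends[[i]])
    }
    sel <- which(!is.na(plants$ortholog))
    truth_b <- plants[sel, , drop = FALSE]
    if (nrow(truth_b)) {
      truth_b$start <- mapply(function(chr, x) a2b(chr, x),
                              truth_b$chrom, truth_b$start)
      truth_b$end <- mapply(function(chr, x) a2b(chr, x),
                            truth_b$chrom, truth_b$end)
      truth_b$plant_id <- sub("^plant", "plantB", truth_b$plant_id)
    }
    est_rows_b <- lapply(seq_len(nrow(truth_b)), function(i)
      plant_ests(truth_b$plant_id[i], truth_b$chrom[i],
                 chrom_len_b[truth_b$chrom[i]], truth_b$start[i],
                 truth_b$end[i], truth_b$n_ests[i]))
    psl_b <- if (length(est_rows_b)) do.call(rbind, est_rows_b) else empty_psl()
    peaks_b <- list()
    for (i in seq_len(nrow(truth_b))) {
      o <- truth_b$orientation[i]
      if (o %in% c("forward", "bidirectional"))
        peaks_b[[length(peaks_b) + 1L]] <- data.frame(
          chrom = truth_b$chrom[i], start = truth_b$start[i] + 5L,
          end = truth_b$start[i] + 15L,
          name = paste0("pfw_", truth_b$plant_id[i]), score = 1L,
          strand = "+", stringsAsFactors = FALSE)
      if (o %in% c("reverse", "bidirectional"))
        peaks_b[[length(peaks_b) + 1L]] <- data.frame(
          chrom = truth_b$chrom[i], start = truth_b$end[i] - 15L,
          end = truth_b$end[i] - 5L,
          name = paste0("prv_", truth_b$plant_id[i]), score = 1L,
          strand = "-", stringsAsFactors = FALSE)
    }
    peaks_b <- if (length(peaks_b)) do.call(rbind, peaks_b) else peaks[0, ]
    files$psl_b <- file.path(out_dir, "ests_B.psl")
    write_psl(psl_b, files$psl_b)
    files$genes_b <- file.path(out_dir, "genes_B.genePred")
    write_genepred(genes_b, files$genes_b)
    files$cage_b <- file.path(out_dir, "cage_B.bed")
    write_bed(peaks_b, files$cage_b)
    files$chains_ab <- file.path(out_dir, "chain_AtoB.chain")
    write_chain(chains_ab, files$chains_ab)
    files$chains_ba <- file.path(out_dir, "chain_BtoA.chain")
    write_chain(chains_ba, files$chains_ba)
  }

  # ---- truth assembly ----
  plants$genome <- "A"
  truth_clusters <- plants
  if (!is.null(truth_b) && nrow(truth_b)) {
    truth_b$genome <- "B"
    truth_clusters <- rbind(truth_clusters, truth_b)
  }
  numts <- if (length(numts)) do.call(rbind, numts) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  n_clusters_expected <- if (cfg$spliced_decoy_frac == 0 &&
                               cfg$mismatch_decoy_frac == 0)
    nrow(plants) else NA_integer_
  funnel_a <- c(input = nrow(psl_a),
                after_haplotype = nrow(psl_a) - cfg$n_hap_decoys,
                after_gap = nrow(psl_a) - cfg$n_hap_decoys -
                  cfg$n_gap_decoys - conv_spliced,
                after_mismatch = nrow(psl_a) - cfg$n_hap_decoys -
                  cfg$n_gap_decoys - conv_spliced -
                  cfg$n_mismatch_decoys - conv_mm,
                after_numt = nrow(psl_a) - cfg$n_hap_decoys -
                  cfg$n_gap_decoys - conv_spliced -
                  cfg$n_mismatch_decoys - conv_mm - cfg$n_numt_decoys)
  funnel_a["unspliced_ests"] <- funnel_a[["after_numt"]]
  funnel_a["clusters"] <- n_clusters_expected

  # ---- write genome A bundle ----
  files$psl_a <- file.path(out_dir, "ests_A.psl")
  write_psl(psl_a, files$psl_a)
  files$genes_a <- file.path(out_dir, "genes_A.genePred")
  write_genepred(genes, files$genes_a)
  files$numts_a <- file.path(out_dir, "numts_A.bed")
  write_bed(numts, files$numts_a)
  files$cage_a <- file.path(out_dir, "cage_A.bed")
  write_bed(peaks, files$cage_a)
  cell_dir <- file.path(out_dir, "cells_A")
  dir.create(cell_dir, showWarnings = FALSE)
  files$cells_a <- vapply(seq_len(cfg$n_cell_types), function(cl) {
    p <- file.path(cell_dir, sprintf("cell_%02d.bed", cl))
    write_bed(peaks[sort(unique(cell_sets[[cl]])), , drop = FALSE], p)
    p
  }, character(1))
  files$chromatin_a <- file.path(out_dir, "chromatin_A.bed")
  write_bed(segs, files$chromatin_a)
  files$rnaseq_a <- c(file.path(out_dir, "rnaseq_A_1.bedGraph"),
                      file.path(out_dir, "rnaseq_A_2.bedGraph"))
  write_bedgraph(track1, files$rnaseq_a[1L])
  write_bedgraph(track2, files$rnaseq_a[2L])
  files$conservation_a <- file.path(out_dir, "phastcons_A.wig")
  write_wiggle(cons, files$conservation_a)
  files$truth_clusters <- file.path(out_dir, "truth_clusters.tsv")
  write.table(truth_clusters, files$truth_clusters, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files$truth_funnel <- file.path(out_dir, "truth_funnel.tsv")
  write.table(data.frame(stage = names(funnel_a), n = unname(funnel_a)),
              files$truth_funnel, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(list(dir = out_dir, files = files,
                 truth = list(clusters = truth_clusters, funnel_a = funnel_a,
                              decoys = data.frame(kind = decoy_kind,
                                                  stringsAsFactors = FALSE)),
                 excluded_chroms = hap_chrom,
                 chrom_sizes_a = chrom_len, chrom_sizes_b = chrom_len_b,
                 config = cfg),
            class = "uest_scenario")
}

#' @export
print.uest_scenario <- function(x, ...) {
  cat(sprintf("uEST synthetic scenario (seed %d)\n", x$config$seed))
  cat(sprintf("  %d chromosome(s), %d planted cluster(s), two_genomes=%s\n",
              x$config$n_chromosomes, nrow(x$truth$clusters),
              x$config$two_genomes))
  cat(sprintf("  bundle: %s\n", x$dir))
  invisible(x)
}

#' Generate the worked-toy bundle
#'
#' A fixed, human-readable ~50-kb two-genome scenario with exactly one
#' cluster of every class (including one deliberately ambiguous
#' `NO_CLASS` plant), one CAGE uaRNA and one same-class ortholog pair,
#' plus one decoy alignment per filter.  Used by the documentation and as
#' a frozen fixture in the tests.
#'
#' @param out_dir output directory (default a fresh tempdir).
#' @return A `uest_scenario`, see [generate_scenario()].
#' @export
generate_worked_toy <- function(out_dir = tempfile("uest_toy_")) {
  generate_scenario(scenario_config(seed = 42L, n_genes = 1L, n_igr = 1L,
                                    plant_no_class = TRUE, two_genomes = TRUE,
                                    n_ortholog = 1L, n_uarna = 1L,
                                    n_cell_types = 3L,
                                    n_gap_decoys = 1L, n_mismatch_decoys = 1L,
                                    n_numt_decoys = 1L, n_hap_decoys = 1L),
                    out_dir)
}
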