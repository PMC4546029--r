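# Independent oracles used to cross-check the package implementations.
# Each is deliberately written by a different route than the package code:
# brute-force all-pairs graphs, per-base painting, per-base chain walking.

# --- clustering: all-pairs graph + igraph connected components -------------
oracle_cluster <- function(ests, join = 30L, minsize = 3L) {
  out <- list()
  for (chr in unique(ests$chrom)) {
    e <- ests[ests$chrom == chr, , drop = FALSE]
    n <- nrow(e)
    edges_from <- integer(0); edges_to <- integer(0)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        j <- (i + 1L):n
        gap <- pmax(0L, pmax(e$start[i], e$start[j]) - pmin(e$end[i], e$end[j]))
        hit <- j[gap <= join]
        edges_from <- c(edges_from, rep(i, length(hit)))
        edges_to <- c(edges_to, hit)
      }
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges_from), to = as.character(edges_to)),
      directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
    comp <- igraph::components(g)$membership[as.character(seq_len(n))]
    for (k in unique(comp)) {
      idx <- which(comp == k)
      if (length(idx) < minsize) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(e$start[idx]), end = max(e$end[idx]),
        n_members = length(idx),
        members = paste(sort(e$est_id[idx]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_members = integer(0), members = character(0))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- classification: per-base painting + an independent rule reading -------
# paints every base around one gene with (component kind, instance index)
# and separate UTR flags, then counts painted bases inside the cluster
oracle_paint_gene <- function(gene, flank) {
  lo <- max(0L, gene$tx_start - flank)
  hi <- gene$tx_end + flank
  pos <- lo:(hi - 1L)
  kind <- rep(NA_character_, length(pos))
  inst <- rep(0L, length(pos))
  es <- gene$exon_starts[[1L]]; ee <- gene$exon_ends[[1L]]
  for (k in seq_along(es)) {
    sel <- pos >= es[k] & pos < ee[k]
    kind[sel] <- "exon"; inst[sel] <- k
  }
  if (length(es) > 1L) {
    for (k in seq_len(length(es) - 1L)) {
      sel <- pos >= ee[k] & pos < es[k + 1L]
      kind[sel] <- "intron"; inst[sel] <- k
    }
  }
  left <- pos < gene$tx_start
  right <- pos >= gene$tx_end
  if (gene$strand == "+") {
    kind[left] <- "upstream"; kind[right] <- "downstream"
  } else {
    kind[left] <- "downstream"; kind[right] <- "upstream"
  }
  inst[left | right] <- 1L
  utr5 <- utr3 <- rep(FALSE, length(pos))
  if (gene$cds_start < gene$cds_end) {
    exonic <- !is.na(kind) & kind == "exon"
    l <- exonic & pos < gene$cds_start
    r <- exonic & pos >= gene$cds_end
    if (gene$strand == "+") { utr5 <- l; utr3 <- r } else { utr5 <- r; utr3 <- l }
  }
  list(pos = pos, kind = kind, inst = inst, utr5 = utr5, utr3 = utr3)
}

# independent reading of the class rules over painted base counts
oracle_classify_vs_gene <- function(cstart, cend, gene, flank, thr) {
  p <- oracle_paint_gene(gene, flank)
  sel <- p$pos >= cstart & p$pos < cend
  key <- paste(p$kind[sel], p$inst[sel])
  key <- key[!is.na(p$kind[sel])]
  counts <- table(key)
  hits <- names(counts)[counts > thr]
  parts <- strsplit(hits, " ", fixed = TRUE)
  kinds <- vapply(parts, `[[`, character(1), 1L)
  insts <- as.integer(vapply(parts, `[[`, character(1), 2L))
  exon_i <- sort(insts[kinds == "exon"])
  intron_i <- sort(insts[kinds == "intron"])
  up <- "upstream" %in% kinds
  down <- "downstream" %in% kinds
  # UTR hits follow the same per-instance threshold (instance = exon index)
  per_inst_hit <- function(flag) {
    cnt <- table(p$inst[sel & flag])
    any(cnt > thr)
  }
  utr5 <- per_inst_hit(p$utr5)
  utr3 <- per_inst_hit(p$utr3)
  has_e <- length(exon_i) > 0L; has_i <- length(intron_i) > 0L
  if (has_e && !has_i && !up && !down) return("TEX")
  if (!has_e && has_i && !up && !down) return("TIN")
  if (has_e && length(intron_i) == 1L && !up && !down) {
    ii <- intron_i
    if (identical(exon_i, c(ii, ii + 1L))) return("rI")
    if (length(exon_i) == 1L && exon_i %in% c(ii, ii + 1L)) {
      left_exon <- exon_i == ii
      five_prime <- (gene$strand == "+" && left_exon) ||
        (gene$strand == "-" && !left_exon)
      return(if (five_prime) "5PIN" else "3PIN")
    }
  }
  if (has_e && up && !down && !utr3) return("5R")
  if (has_e && down && !up && !utr5) return("3R")
  if (up && !down && !has_e && !has_i) return("UT")
  if (down && !up && !has_e && !has_i) return("DT")
  "NO_CLASS"
}

# --- lifting: per-base chain walk ------------------------------------------
# maps every base of the interval independently through every chain, then
# applies the fraction / single-chain rules
oracle_lift <- function(interval, chains, min_frac = 0.95) {
  bases <- interval$start:(interval$end - 1L)
  per_chain <- list()
  for (ch in chains) {
    if (ch$t_name != interval$chrom) next
    mapped <- rep(NA_integer_, length(bases))
    t <- ch$t_start; q <- ch$q_start
    for (k in seq_len(nrow(ch$blocks))) {
      size <- ch$blocks[k, "size"]
      # each base inside an aligned block maps by its own offset
      idx <- which(bases >= t & bases < t + size)
      mapped[idx] <- q + (bases[idx] - t)
      t <- t + size + ch$blocks[k, "dt"]
      q <- q + size + ch$blocks[k, "dq"]
    }
    ok <- !is.na(mapped)
    if (!any(ok)) next
    qpos <- mapped[ok]
    if (ch$q_strand == "-") qpos <- ch$q_size - qpos - 1L
    per_chain[[length(per_chain) + 1L]] <- list(
      chrom = ch$q_name, start = min(qpos), end = max(qpos) + 1L,
      mapped_frac = sum(ok) / length(bases), chain_id = ch$chain_id)
  }
  good <- Filter(function(r) r$mapped_frac >= min_frac, per_chain)
  if (length(good) != 1L) return(NULL)
  good[[1L]]
}

# --- CAGE orientation: explicit per-peak loop ------------------------------
oracle_orient <- function(cluster, peaks, window = 84L) {
  fw <- FALSE; rv <- FALSE
  fw_end <- min(cluster$end, cluster$start + window)
  rv_start <- max(cluster$start, cluster$end - window)
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != cluster$chrom) next
    if (peaks$strand[i] == "+" &&
          peaks$start[i] < fw_end && peaks$end[i] > cluster$start) fw <- TRUE
    if (peaks$strand[i] == "-" &&
          peaks$start[i] < cluster$end && peaks$end[i] > rv_start) rv <- TRUE
  }
  if (fw && rv) "bidirectional" else if (fw) "forward" else if (rv) "reverse" else "none"
}

# --- filters: independent per-alignment re-check on raw PSL fields ---------
oracle_filter_counts <- function(psl, numts, excluded, max_gap = 30L,
                                 max_mm = 0.05) {
  n <- nrow(psl)
  keep <- rep(TRUE, n)
  counts <- c(input = n)
  keep <- keep & !(psl$tName %in% excluded)
  counts["after_haplotype"] <- sum(keep)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    sizes <- as.integer(strsplit(psl$blockSizes[i], ",")[[1L]])
    starts <- as.integer(strsplit(psl$tStarts[i], ",")[[1L]])
    g <- 0L
    if (length(sizes) > 1L)
      for (k in 2:length(sizes)) g <- max(g, starts[k] - starts[k - 1L] - sizes[k - 1L])
    if (g > max_gap) keep[i] <- FALSE
  }
  counts["after_gap"] <- sum(keep)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    den <- psl$matches[i] + psl$repMatches[i] + psl$misMatches[i]
    if (den > 0 && psl$misMatches[i] / den > max_mm) keep[i] <- FALSE
  }
  counts["after_mismatch"] <- sum(keep)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (k in seq_len(nrow(numts))) {
      if (numts$chrom[k] == psl$tName[i] &&
            numts$start[k] < psl$tEnd[i] && numts$end[k] > psl$tStart[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  counts["after_numt"] <- sum(keep)
  counts["unspliced_ests"] <- sum(keep)
  counts
}

# --- conservation: per-base value lookup -----------------------------------
oracle_mean_score <- function(interval, track) {
  vals <- numeric(0)
  for (b in interval$start:(interval$end - 1L)) {
    row <- which(track$chrom == interval$chrom & track$start <= b & track$end > b)
    if (length(row)) vals <- c(vals, track$value[row[1L]])
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# --- in-range mapping: all-pairs loop --------------------------------------
oracle_in_range <- function(clusters, genes, flank = 5000L) {
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    for (j in seq_len(nrow(genes))) {
      if (clusters$chrom[i] != genes$chrom[j]) next
      lo <- max(0L, genes$tx_start[j] - flank)
      hi <- genes$tx_end[j] + flank
      if (clusters$start[i] < hi && clusters$end[i] > lo)
        out[[length(out) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], gene_id = genes$gene_id[j],
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(0), gene_id = character(0))
  res[order(res$cluster_id, res$gene_id), , drop = FALSE]
}
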