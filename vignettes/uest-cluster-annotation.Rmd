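---
title: "Annotating unspliced EST clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating unspliced EST clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uestr)
```

## The problem

Expressed sequence tags are single-pass cDNA reads aligned to a genome.
Most transcript annotation is driven by spliced alignments, whose
intron gaps anchor gene structure.  Alignments *without* intron-sized
gaps — unspliced ESTs — are usually discarded, yet in aggregate they
mark a distinct transcriptome component: intronic transcripts, 3'UTR
extensions and UTR-associated RNAs, and intergenic unspliced RNAs.  Two
properties make this data awkward: single reads carry no strand
information once splice junctions are absent, and single-read evidence
is noisy.  The pipeline in this package addresses both by aggregating
reads into clusters, classifying clusters purely positionally against
an existing gene annotation, and only then attaching orientation and
transcription evidence from independent assays (CAGE, chromatin state,
RNA-seq) and comparative signals (chain lifting, conservation scores).

All coordinates in the package are 0-based half-open (BED convention);
the PSL, genePred, chain, bedGraph and BED inputs already use that
convention and wiggle 1-based starts are converted on read.  Chromosome
names are matched by exact string equality — aliasing `chr1`/`1`
silently would hide input mix-ups.

## Filtering and clustering

An alignment survives the filters when

* its chromosome is not excluded (alternative haplotypes would count
  identical ESTs twice);
* its largest single target-side gap is ≤ `max_gap_nt` (30 nt).  The
  threshold rests on the observation that genuine introns below ~30 nt
  are vanishingly rare, so a larger gap indicates a spliced or
  misaligned read.  We read "gap" as the *largest single* intron-like
  event; a variant reading that caps the *summed* inserted bases is
  available via `gap_mode = "summed"` since the two differ for
  multi-gap alignments;
* its mismatch fraction `misMatches / (matches + repMatches +
  misMatches)` — per aligned base, the standard PSL reading — is
  ≤ `max_mismatch_frac` (5 %);
* it does not overlap a NUMT region by ≥ 1 nt.  Mitochondrial
  transcripts are unspliced, so reads from them that map to nuclear
  mitochondrial insertions are indistinguishable from genuine nuclear
  transcription and are removed outright.

The funnel report records the count surviving each filter, in order, so
losses are attributable per rule.

Clustering then joins two surviving ESTs when they overlap or are
separated by at most `cluster_join_nt` (30 nt): with half-open
coordinates an EST ending at 100 joins one starting at 130 (gap 30) but
not at 131.  Clusters are connected components of this relation,
computed by a sorted sweep per chromosome, which is order-independent
and equivalent to the all-pairs union-find (the test suite checks this
equivalence against an independent igraph implementation).  Components
with fewer than `min_cluster_size` (3) members are dropped as likely
artifacts.  Strand is ignored throughout — EST reading direction is
unknown at this stage.

## Positional classification

Each gene model is decomposed into exons, introns, exonic 5'/3'UTR
pieces, and 5-kb upstream/downstream flanks, all strand-aware.  A
cluster is classified against every gene whose span-plus-flanks it
touches by ≥ 1 nt.  A component instance counts as overlapped only when
the overlap is *strictly greater than* `min_component_overlap_nt`
(20 nt) — a guard against small inaccuracies in annotated component
borders.  The per-instance reading matters: a cluster touching two
introns of one gene while crossing the intervening exon by ≤ 20 nt
yields the component set {intron} and is classified TIN; the rule list
has no explicit multi-instance case, and the per-instance reading is
the minimal consistent extension.  We apply the same 20-nt threshold to
flank overlaps (UT/DT) for uniformity, since no separate threshold is
stated for them.

The component set then maps to one of 11 exhaustive, mutually exclusive
classes (see the README table).  Three decisions deserve notice:

* **TEX** counts UTR bases as exonic; the 5'/3'UTR sub-labels are
  consulted only by the 5R/3R rules and the uaRNA caller.
* **5R/3R** are implemented literally from their definitions: 5R
  requires exon + upstream overlap and *no* downstream or 3'UTR
  overlap; intronic overlap does not disqualify it (the definition does
  not mention introns), and symmetrically for 3R.
* **Multi-gene conflicts**: per-gene classes are computed first, then
  the set is reduced — unanimity keeps the class; exactly one genic
  class (TEX, TIN, 5PIN, 3PIN, rI, 5R, 3R) conflicting only with UT/DT
  keeps the genic class (otherwise gene-dense regions would be
  unclassifiable); anything else is NO_CLASS.  Overlapping isoforms are
  deliberately kept as independent gene models and resolved by this
  same mechanism rather than pre-merged, because the classification is
  defined per overlapping gene.

A strand flip of the gene swaps 5PIN↔3PIN, 5R↔3R and UT↔DT on the same
geometry; this antisymmetry and the full rule table are property-tested
against an independent per-base painting oracle that labels every
genomic position and re-derives the class from painted base counts.

## Evidence overlays

**CAGE orientation.**  A stranded TSS peak overlapping the first 84 nt
of a cluster by ≥ 1 nt is forward evidence; one overlapping the last
84 nt on the minus strand is reverse evidence.  Forward-only evidence
orients the cluster forward, reverse-only reverse; both at once mark a
likely bidirectional locus, which is excluded from orientation-based
analyses; neither leaves it unoriented.  The 84-nt window is the
established cutoff for associating a TSS peak with a transcript end in
this setting.  For clusters shorter than 84 nt the windows are clipped
to the cluster rather than the cluster being skipped — clipping keeps
the definition total and changes nothing for the common case.  Peak
overlap uses ≥ 1 nt, not the 20-nt rule, which is stated only for gene
components.

**Expression breadth** runs the same orientation call once per
cell-type peak set and counts cell types giving an unambiguous
(forward/reverse) orientation; the count is invariant to cell-type
order.

**Chromatin support** takes segmentations from any number of cell lines
together (cluster definitions are themselves composites over many
tissues) and flags a cluster when a TSS-state or transcribed-state
segment from at least one cell line overlaps it by ≥ 1 nt.  Adding a
cell line can set flags but never clear them.

**RNA-seq support** interprets each bedGraph interval's value as a read
count and sums the counts of intervals intersecting the cluster within
one library; a cluster is supported when that sum reaches
`min_rnaseq_reads` (10) in *at least one* library — the threshold is
per library and never summed across libraries.  The exact intersection
semantics of the original bedGraph processing are not recoverable, so
this summed-count reading is fixed here and exposed through the config.

## uaRNA calling

A uaRNA candidate is a cluster that (a) overlaps the 3'UTR of at least
one in-range gene by > 20 nt, (b) overlaps *no* in-range gene's 5'UTR
by > 20 nt — we apply (b) to all in-range genes, the stricter of the
two possible readings — and (c) carries its own TSS evidence: an
unambiguous CAGE orientation via the 84-nt end windows, or a ≥ 1 nt
overlap with a TSS-state chromatin segment.  5'-side uaRNAs are not
called: at the 5' end the host gene's own TSS cannot be distinguished
from that of an embedded transcript.  CAGE-based and chromatin-based
call sets can be intersected with `intersect_calls()`.

## Orthology by chain lifting

`lift_interval()` maps each base falling in an aligned chain block by
its block offset and returns the hull of mapped bases on the target
genome; minus-strand chains are converted to forward coordinates.  The
lift fails when fewer than `min_mapped_frac` of the bases map through
the best chain, or when more than one chain exceeds that threshold
(ambiguous placement).  The default 0.95 is the established minimum
match fraction for coordinate conversion between assemblies; no setting
was stated for the original analysis, so the default is exposed as a
parameter.  Cluster pairing lifts genome A clusters onto genome B,
pairs images with B clusters overlapping ≥ 1 nt, repeats in the B→A
direction, and unions the two pair sets, recording which direction(s)
detected each pair — the two directions genuinely differ when the
chains are not exact inverses.  No post-hoc coordinate correction is
applied.

## Conservation summaries

`mean_score()` averages a per-base score track over the *scored* bases
of an interval — unscored bases are excluded from the denominator, not
imputed as zero (the alternative is not recoverable from the original
description; exclusion matches the usual covered-bases averaging).
Values are expected in [0, 1] (posterior probabilities of negative
selection); out-of-range values warn but are used, since real tracks
contain rounding slop.  Per-class summaries take the mean over clusters
of per-cluster means, with an `AVG` row that is the *unweighted* mean
of the class means (not the pooled cluster mean), TEX optionally
subdivided by CDS overlap (fully / partially / not in coding sequence),
and IGR clusters removable via a coding-signal hit list.  Equality with
per-base brute-force averaging is asserted to 1e-12.

## The synthetic-data generator

`generate_scenario()` is the package's test bed and defines the
conditions under which the pipeline is validated.  Per gene it lays out
four exons (lengths log-normal around 320 nt, clamped to the minima the
planted geometry needs) and three introns (log-normal around 1 kb),
alternating strands, with a 120-nt 5'UTR and a ≥ 200-nt 3'UTR, and
plants one cluster of every genic class with margins far beyond the
decision thresholds: deciding overlaps of 40–100 nt (vs the 20-nt
rule), inter-plant separations of ≥ 40 nt (vs the 30-nt join), IGR
plants > 5 kb outside every flank.  Members are 3–6 staggered
single-block ESTs whose union is exactly the planted interval.  Decoy
alignments each violate exactly one filter (gap 200 nt, 8 % mismatches,
NUMT overlap, haplotype chromosome), which is what makes the funnel
ledger exact.  Orientations are drawn per cluster and realised as
~10-nt stranded peaks just inside the relevant end window, with
per-cell-type subsets realising a planted expression breadth.  Genome B
is genome A transformed through indel-bearing chains (indels of
50–400 nt confined to unoccupied gaps, so planted features always lie
inside aligned blocks), with a chosen subset of plants mirrored as
ortholog pairs.  The conservation track is a 20-nt-step wiggle at
baseline 0.1 plus 0.3 times the exonic fraction of each window plus
Gaussian noise (sd 0.02).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: ragged real EST boundaries (planted unions
are exact, so recovered hulls match ground truth to the base),
overlapping transcript isoforms, internally-primed artifact reads,
repeat-driven multi-mapping, chain rearrangements
(inversions/translocations; generator chains are colinear and
strand-preserving, though minus-strand chains are unit-tested
separately), and any sequence content at all — only coordinates and
counts matter to the pipeline.

The determinism contract: one seed flows through a single local RNG
(global random state is saved and restored), so a configuration
reproduces its bundle byte-for-byte, and the pipeline itself embeds no
timestamps, so identical inputs give byte-identical outputs.

## Problem sizes in the test suite

The suite validates classification on 200+ random gene/cluster layouts
(including 19–22-nt boundary snaps), clustering on 50 layouts of up to
5,000 intervals against the all-pairs oracle, lifting on 100+ random
chains (both query strands) against a per-base mapper, and the full
two-genome recovery on one 2-Mb-per-genome scenario with 60 genes, 600
planted clusters, 50 uaRNAs and 100 ortholog pairs at zero noise —
sizes chosen so the whole suite runs in a few minutes on one CPU while
still exercising every rule boundary.  A frozen ~50-kb "worked toy"
(one cluster per class, one uaRNA, one ortholog pair, one decoy per
filter) is compared byte-identically against committed outputs.

## Known limitations

* Classification is per-transcript; isoforms of one locus are not
  collapsed, so transcript-dense annotations push clusters toward
  NO_CLASS — consistent with the definition, but worth knowing.
* Cluster boundaries come from EST hulls; real 5'/3' transcript ends
  are not estimated, which biases the 84-nt window placement on real
  (ragged) data in ways the synthetic tests cannot reveal.
* `lift_interval()` returns the hull on a single chain; split mappings
  across chains are rejected rather than stitched.
* The bedGraph read-count reading of RNA-seq support is one of several
  defensible semantics; with fragmentary coverage tracks the summed
  value is only a proxy for read count.
* External structure/coding predictors are out of scope; their hit
  lists are ingested as plain interval masks (`coding_hits`).
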