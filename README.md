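# uestr

Annotation and comparative analysis of **unspliced EST clusters** — the
layer of the transcriptome formed by expressed-sequence-tag alignments
that carry no intron-sized gap.  Merged into clusters, unspliced ESTs
outline intronic, UTR-associated and intergenic unspliced long RNAs that
splice-junction-driven annotation misses.  `uestr` is for genome
annotators and non-coding-RNA researchers who want to mine EST (or
EST-like) alignment tracks for this signal and ask where those
transcripts sit relative to known genes, whether they are independently
transcribed, and whether they are conserved between two species.

## What it computes

Starting from a PSL alignment track and a genePred gene set, the pipeline

1. **filters** alignments: drops alternative-haplotype chromosomes,
   alignments whose largest genomic gap exceeds 30 nt (spliced or
   intron-like), alignments with > 5 % mismatched bases, and alignments
   overlapping NUMT regions (nuclear copies of mitochondrial DNA);
2. **clusters** the survivors: ESTs that overlap or lie within 30 nt of
   each other join the same cluster; clusters need ≥ 3 members;
3. **classifies** every cluster against each gene within 5 kb, using
   component overlaps that only count above 20 nt, into one of 11
   mutually exclusive classes:

   | class | meaning |
   |-------|---------|
   | TEX   | totally exonic (UTR bases count as exon) |
   | TIN   | totally intronic |
   | 5PIN / 3PIN | one adjoining exon–intron pair, exon 5' / 3' of the intron |
   | rI    | one intron plus both adjacent exons (retained intron) |
   | 5R / 3R | exon + upstream / downstream 5-kb flank, clean on the other side |
   | UT / DT | upstream- / downstream-flank only |
   | IGR   | > 5 kb from every gene |
   | NO_CLASS | conflicting evidence (a conflict with UT/DT only is resolved in favour of the genic class) |

4. **overlays evidence**: reading direction from stranded CAGE TSS peaks
   in the 84-nt end windows (forward / reverse / bidirectional / none),
   expression breadth across per-cell-type peak sets, chromatin-state
   support (TSS / transcribed segments in any cell line), and RNA-seq
   support (≥ 10 reads in at least one library);
5. **calls 3'UTR-associated RNAs (uaRNAs)**: clusters overlapping a
   host gene's 3'UTR (> 20 nt) but no 5'UTR, with their own TSS evidence
   from CAGE or chromatin;
6. **pairs orthologs** across two genomes by lifting cluster coordinates
   through UCSC chain files in both directions (≥ 95 % of bases on a
   single chain) and overlapping the images with the other genome's
   clusters;
7. **summarises conservation**: per-cluster mean of a per-base
   conservation score track (phastCons-style, averaged over scored bases
   only) and per-class means against intron / exon / genome backgrounds.

A first-class synthetic-data generator (`generate_scenario()`) lays out
genomes with planted clusters of every class, decoy alignments that each
violate exactly one filter, CAGE/chromatin/RNA-seq evidence, indel-bearing
chains relating two genomes, and a conservation track elevated over exons
— all with exported ground truth, so the entire pipeline is testable with
no downloads.

## Worked example

The "worked toy" is a deterministic ~50-kb two-genome bundle with one
planted cluster of every class, one uaRNA, one ortholog pair and one
decoy alignment per filter:

```r
library(uestr)
scn <- generate_worked_toy()
res <- run_all(scn$files, "toy_out", excluded_chroms = scn$excluded_chroms)

res$funnel
#> uEST filter funnel (surviving counts)
#>   input            51
#>   after_haplotype  50
#>   after_gap        49
#>   after_mismatch   48
#>   after_numt       47
#>   unspliced_ests   47
#>   clusters         11

class_summary(res$classes$class)
#>  TEX  TIN  5PIN  3PIN  rI  5R  3R  UT  DT  IGR  NO_CLASS
#>    1    1     1     1   1   1   1   1   1    1         1

res$uarna
#>   cluster_id host_genes evidence orientation
#> 1    uc00008       g001     cage     forward

res$orthologs
#>   cluster_a cluster_b detected_by same_class
#> 1   uc00005   uc00001        both       TRUE
```

The funnel loses exactly one alignment per planted decoy (haplotype, gap,
mismatch, NUMT), the 47 clean ESTs form the 11 planted clusters, the 3R
cluster with a forward CAGE peak is the single uaRNA call, and the one
mirrored plant is recovered as a same-class ortholog pair in both lift
directions.  `run_all()` writes each stage as a flat file plus a
`MANIFEST`; `inst/scripts/uest.R` wraps `simulate` and `run-all` for the
shell.

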