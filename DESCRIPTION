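Package: uestr
Title: Annotation and Comparative Analysis of Unspliced EST Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining unspliced expressed sequence tag (EST)
    alignments for evidence of unspliced long non-coding transcripts.
    Filters spliced and low-quality alignments from PSL alignment tracks,
    merges surviving unspliced ESTs into clusters, classifies each cluster
    by its position relative to annotated gene models (intronic, exonic,
    partially intronic, UTR-proximal, upstream/downstream, intergenic),
    overlays orthogonal evidence from CAGE transcription start site peaks,
    chromatin-state segmentations and RNA-seq coverage, calls 3'UTR-associated
    RNA candidates, pairs clusters across species through UCSC chain based
    coordinate lifting, and summarizes per-base conservation scores per
    cluster class. Includes a synthetic-genome generator that plants clusters
    of every class with known ground truth so the whole pipeline can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
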