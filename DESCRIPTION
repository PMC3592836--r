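Package: hybridaction
Title: Gene-Action Classification for Hybrid Versus Parent Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the transcriptome of an F1 hybrid with its
    two parental lines from single-library RNA-seq: FPKM quantification and
    gene-locus coverage summaries, read-mapping and alignment-score
    statistics, count-based differential-expression calls for the three
    pairwise comparisons, partition of differential transcripts into the
    seven Venn subgroups, classification of every hybrid differential
    transcript into five gene-action modes (underdominance, low- and
    high-parent dominance, additivity, overdominance), natural-log
    fold-change binning, and one-tailed Fisher exact GO-term
    over-representation with Benjamini-Hochberg control. A fully synthetic
    three-sample study generator with planted gene-action modes and planted
    GO enrichment makes every stage testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
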